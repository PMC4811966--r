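#' Specify a genotype/phenotype simulation design
#'
#' Encodes one cell of the simulation grid: sample size, number of SNPs,
#' minor-allele frequency, the AR(1) correlation of the latent Gaussian
#' process that induces linkage disequilibrium, the causal set and its total
#' marginal variance, the structural-zero probability of the phenotype, and
#' the NB dispersion.
#'
#' @param n Sample size.
#' @param k Number of SNPs (default 50).
#' @param maf Minor-allele frequency, in (0, 0.5) (default 0.05).
#' @param rho Latent AR(1) correlation in `[0, 1)`; 0 gives independent
#'   SNPs, 0.5 moderate LD, 0.9 high LD.
#' @param causal_idx Indices of causal SNPs; defaults to SNPs 1, 11, 21,
#'   31, 41 when `k >= 41` (every tenth SNP), else the first
#'   `min(5, k)` SNPs.
#' @param h_total Sum of causal marginal variances `h = sum h_j^2`; 0 gives
#'   the null design.
#' @param zero_inflation Structural-zero probability `pi` in `[0, 1)`
#'   (default 0.5, an intercept-only zero model).
#' @param theta NB dispersion of the count component (default 1).
#' @param beta0 Count-model intercept of the generator (default 0).
#' @param coding `"additive"` (0/1/2 minor-allele count) or `"codominant"`
#'   (two indicator columns per SNP at analysis time).
#' @param seed Optional seed recorded with the design.
#' @return A `sim_design` object.
#' @export
simulation_design <- function(n, k = 50L, maf = 0.05, rho = 0,
                              causal_idx = NULL, h_total = 0.05,
                              zero_inflation = 0.5, theta = 1, beta0 = 0,
                              coding = c("additive", "codominant"),
                              seed = NULL) {
  coding <- match.arg(coding)
  if (n < 1 || k < 1) stop("n and k must be positive")
  if (maf <= 0 || maf >= 0.5) stop("maf must lie in (0, 0.5)")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (zero_inflation < 0 || zero_inflation >= 1) stop("zero_inflation must lie in [0, 1)")
  if (theta <= 0) stop("theta must be positive")
  if (h_total < 0) stop("h_total must be nonnegative")
  if (is.null(causal_idx))
    causal_idx <- if (k >= 41L) c(1L, 11L, 21L, 31L, 41L) else seq_len(min(5L, k))
  causal_idx <- as.integer(causal_idx)
  if (h_total > 0 && !length(causal_idx)) stop("causal set empty with h_total > 0")
  if (length(causal_idx) && (any(causal_idx < 1L) || any(causal_idx > k)))
    stop("causal_idx out of range")
  structure(list(n = as.integer(n), k = as.integer(k), maf = maf, rho = rho,
                 causal_idx = causal_idx, h_total = h_total,
                 zero_inflation = zero_inflation, theta = theta, beta0 = beta0,
                 coding = coding, seed = seed),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "simulation design: n = %d, k = %d SNPs (MAF %.3g, AR(1) rho = %.2g)\n",
    x$n, x$k, x$maf, x$rho))
  cat(sprintf("  causal: %s, h = %.3g, zero inflation = %.2g, theta = %.2g\n",
              paste(x$causal_idx, collapse = "/"), x$h_total,
              x$zero_inflation, x$theta))
  invisible(x)
}

#' Simulate correlated SNP genotypes from a dichotomized latent AR(1) process
#'
#' Each haplotype comes from a latent standard-normal AR(1) vector
#' (`Cov(Z_i, Z_j) = rho^|i-j|`, generated by the exact recursion) carrying
#' the minor allele wherever the latent value falls below the MAF-quantile
#' `qnorm(maf)`; two independent haplotypes are summed to an additive 0/1/2
#' genotype, so the expected allele frequency equals `maf` and neighboring
#' SNPs are in LD controlled by `rho`.
#'
#' @param design A [simulation_design()].
#' @param seed Optional seed (overrides `design$seed`).
#' @return A `genotype_matrix`: integer matrix `G` (`n x k`, entries 0/1/2),
#'   estimated column MAFs, and the generating design.
#' @export
simulate_genotypes <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  seed <- seed %||% design$seed
  if (!is.null(seed)) set.seed(seed)
  n <- design$n; k <- design$k
  thr <- stats::qnorm(design$maf)
  hap <- function() {
    Z <- matrix(stats::rnorm(n * k), n, k)
    if (design$rho > 0 && k > 1L) {
      a <- sqrt(1 - design$rho^2)
      for (j in 2:k) Z[, j] <- design$rho * Z[, j - 1L] + a * Z[, j]
    }
    Z < thr
  }
  G <- hap() + hap()
  storage.mode(G) <- "integer"
  colnames(G) <- paste0("snp", seq_len(k))
  structure(list(G = G, maf_hat = colMeans(G) / 2, design = design),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, mean MAF-hat = %.4f\n",
              nrow(x$G), ncol(x$G), mean(x$maf_hat)))
  invisible(x)
}

#' Sample genotypes i.i.d. from per-SNP genotype-class frequencies
#'
#' A frequency-based categorical sampler producing unlinked genotypes whose
#' class frequencies match a supplied `k x 3` table (common homozygote,
#' heterozygote, minor homozygote). A synthetic stand-in for drawing real
#' genotype panels that are not distributed with the package.
#'
#' @param freqs `k x 3` matrix of genotype-class probabilities (rows sum
#'   to 1).
#' @param n Number of individuals.
#' @param seed Optional seed.
#' @return Integer genotype matrix (`n x k`, entries 0/1/2).
#' @export
simulate_genotypes_freq <- function(freqs, n, seed = NULL) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 3L) stop("freqs must have three columns")
  if (any(freqs < 0) || any(abs(rowSums(freqs) - 1) > 1e-6))
    stop("rows of freqs must be probability vectors")
  if (!is.null(seed)) set.seed(seed)
  G <- vapply(seq_len(nrow(freqs)), function(j)
    sample(0:2, n, replace = TRUE, prob = freqs[j, ]), integer(n))
  colnames(G) <- paste0("snp", seq_len(nrow(freqs)))
  G
}

#' Effect sizes calibrated by equal marginal variances
#'
#' Each causal SNP contributes the same marginal variance
#' `h_j^2 = h_total / n_causal` to the linear predictor, where under
#' additive coding `h_j^2 = 2 * maf * (1 - maf) * beta_j^2`; hence
#' `beta_j = sqrt(h_j^2 / (2 maf (1 - maf)))` (positive sign) for causal
#' SNPs and 0 otherwise.
#'
#' @param design A [simulation_design()].
#' @return Numeric vector of length `k`.
#' @export
effect_sizes_from_h2 <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  beta <- numeric(design$k)
  if (design$h_total > 0) {
    hj2 <- design$h_total / length(design$causal_idx)
    beta[design$causal_idx] <- sqrt(hj2 / (2 * design$maf * (1 - design$maf)))
  }
  beta
}

#' Generate a ZINB phenotype from genotypes
#'
#' Per individual, a latent structural-zero indicator
#' `z_i ~ Bernoulli(pi)` with `pi = zero_inflation` (intercept-only zero
#' model); `y_i = 0` when `z_i = 1`, otherwise
#' `y_i ~ NB(mu_i = exp(beta0 + x_i' beta), theta)`. The latent indicators
#' are retained (attribute `"latent_zero"`) for validation only.
#'
#' @param G A `genotype_matrix` or a plain numeric design matrix (no
#'   intercept).
#' @param beta Effect-size vector matching the columns of `G` (default from
#'   [effect_sizes_from_h2()]).
#' @param design A [simulation_design()] (taken from `G` if absent).
#' @param seed Optional seed.
#' @return A [zic_data()] with attributes `latent_zero`, `true_beta`
#'   (including the intercept) and `design`.
#' @export
simulate_zinb_phenotype <- function(G, beta = NULL, design = NULL, seed = NULL) {
  if (inherits(G, "genotype_matrix")) {
    design <- design %||% G$design
    G <- G$G
  }
  if (is.null(design)) stop("a simulation design is required")
  if (is.null(beta)) beta <- effect_sizes_from_h2(design)
  if (length(beta) != ncol(G)) stop("beta does not match the genotype columns")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G)
  mu <- exp(design$beta0 + drop(G %*% beta))
  z <- stats::rbinom(n, 1L, design$zero_inflation)
  y <- ifelse(z == 1L, 0,
              stats::rnbinom(n, size = design$theta, mu = mu))
  dat <- zic_data(y, G)
  attr(dat, "latent_zero") <- z
  attr(dat, "true_beta") <- c(design$beta0, beta)
  attr(dat, "design") <- design
  dat
}

#' Deterministic replicate stream
#'
#' Replicate `s` is generated under seed `base_seed + s`, with genotypes and
#' phenotype drawn afresh, so any replicate can be regenerated independently
#' of the others.
#'
#' @param design A [simulation_design()].
#' @param base_seed Integer base seed.
#' @param s Replicate index (1-based).
#' @return A [zic_data()] as from [simulate_zinb_phenotype()].
#' @export
replicate_data <- function(design, base_seed, s) {
  set.seed(base_seed + s)
  G <- simulate_genotypes(design, seed = NULL)
  simulate_zinb_phenotype(G, design = design, seed = NULL)
}

#' Generate a list of simulation replicates
#'
#' @param design A [simulation_design()].
#' @param R Number of replicates.
#' @param base_seed Integer base seed; replicate `s` uses `base_seed + s`.
#' @return List of `R` [zic_data()] objects.
#' @export
generate_replicates <- function(design, R, base_seed = 1L) {
  if (R < 1) stop("R must be at least 1")
  lapply(seq_len(R), function(s) replicate_data(design, base_seed, s))
}

#' Expand additive genotypes to codominant indicator pairs
#'
#' Each SNP becomes two indicator columns: heterozygote (`genotype == 1`)
#' and minor homozygote (`genotype == 2`), so `k` SNPs yield `2k` design
#' columns.
#'
#' @param G Integer genotype matrix (entries 0/1/2) or `genotype_matrix`.
#' @return Numeric indicator matrix with `2 * ncol(G)` columns named
#'   `<snp>_het` and `<snp>_hom`.
#' @export
codominant_expand <- function(G) {
  if (inherits(G, "genotype_matrix")) G <- G$G
  if (!all(G %in% 0:2)) stop("genotypes must be coded 0/1/2")
  k <- ncol(G)
  nm <- colnames(G) %||% paste0("snp", seq_len(k))
  out <- matrix(0, nrow(G), 2L * k)
  out[, seq(1L, 2L * k, by = 2L)] <- (G == 1L) * 1
  out[, seq(2L, 2L * k, by = 2L)] <- (G == 2L) * 1
  colnames(out) <- as.vector(rbind(paste0(nm, "_het"), paste0(nm, "_hom")))
  out
}

#' Write genotypes as delimited text
#'
#' @param G Genotype matrix or `genotype_matrix`.
#' @param file Output path.
#' @param sep Field separator.
#' @export
write_genotypes <- function(G, file, sep = "\t") {
  if (inherits(G, "genotype_matrix")) G <- G$G
  utils::write.table(G, file, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a delimited or PLINK-raw-style genotype table
#'
#' Accepts a header row plus 0/1/2 entries (possibly with NA); missing
#' genotypes are filled with the column mean of the observed values.
#'
#' @param file Input path.
#' @param sep Field separator; default any whitespace.
#' @return Numeric genotype matrix.
#' @export
read_genotypes <- function(file, sep = "") {
  tab <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE)
  G <- as.matrix(tab)
  storage.mode(G) <- "double"
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) stop("genotype entries must be 0/1/2 or NA")
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- mean(G[!miss, j])
  }
  G
}

#' Read a simulation design from a YAML or JSON config file
#'
#' Recognized fields are the arguments of [simulation_design()].
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_design` object.
#' @export
read_design <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  # the YAML 1.1 parser reads a bare `n` key as a boolean
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  names(cfg)[names(cfg) == "TRUE"] <- "y"
  known <- names(formals(simulation_design))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown design fields: ", paste(unknown, collapse = ", "))
  do.call(simulation_design, cfg)
}
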