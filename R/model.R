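#' Read a PAML-style amino-acid model file
#'
#' Parses the classical dat layout: 19 lines giving the lower triangle of
#' the symmetric exchangeability matrix (row i holds entries for states
#' 1..i-1), followed by a line of 20 equilibrium frequencies. Lines starting
#' with \code{#} and blank lines are ignored. State order is the PAML
#' amino-acid order A R N D C Q E G H I L K M F P S T W Y V.
#'
#' @param path Path to the dat file.
#' @return List with \code{S} (20x20 symmetric exchangeabilities, zero
#'   diagonal) and \code{freq} (named, sums to 1).
#' @export
read_paml_dat <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  nums <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(nums) < 20) stop("model file too short: ", path)
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (i in 2:20) {
    row <- nums[[i - 1]]
    if (length(row) != i - 1) {
      stop(sprintf("expected %d entries on triangle row %d, found %d",
                   i - 1, i, length(row)))
    }
    S[i, 1:(i - 1)] <- row
  }
  S <- S + t(S)
  freq <- unlist(nums[20:length(nums)])
  if (length(freq) != 20) stop("expected 20 frequencies, found ", length(freq))
  freq <- freq / sum(freq)
  names(freq) <- AA20
  list(S = S, freq = freq)
}

model_file <- function(matrix_name) {
  f <- c(JTT = "jones.dat", WAG = "wag.dat", LG = "lg.dat")[matrix_name]
  if (is.na(f)) stop("unknown matrix name: ", matrix_name)
  system.file("extdata", "models", f, package = "paleofmo", mustWork = TRUE)
}

#' Build an empirical amino-acid substitution model
#'
#' Constructs the calibrated reversible rate matrix
#' \eqn{Q_{ij} = S_{ij}\pi_j} (diagonal set so rows sum to zero, then
#' rescaled so that \eqn{-\sum_i \pi_i Q_{ii} = 1}, i.e. branch lengths are
#' expected substitutions per site), together with K equal-probability
#' discrete-gamma rate categories of shape \code{alpha}. The eigensystem of
#' the symmetrized generator is precomputed for transition probabilities.
#'
#' @param matrix_name One of \code{"JTT"} (default, the Jones matrix),
#'   \code{"WAG"}, \code{"LG"}.
#' @param frequencies_mode \code{"matrix_default"} uses the frequencies
#'   distributed with the matrix; \code{"observed"} (+F) uses amino-acid
#'   frequencies counted from \code{alignment} (gaps/X excluded).
#' @param alpha Gamma shape parameter (> 0); rate variation vanishes as
#'   \code{alpha} grows.
#' @param K Number of discrete rate categories (>= 1).
#' @param alignment Required when \code{frequencies_mode = "observed"}.
#' @param rate_mode \code{"mean"} (bin mean, default) or \code{"median"}
#'   category rates.
#' @return An object of class \code{substitution_model}: \code{S},
#'   \code{freq}, \code{Q}, \code{alpha}, \code{K}, \code{rates}, plus the
#'   eigendecomposition used by \code{\link{transition_matrix}}.
#' @export
build_model <- function(matrix_name = "JTT",
                        frequencies_mode = c("matrix_default", "observed"),
                        alpha = 1.114, K = 4,
                        alignment = NULL,
                        rate_mode = c("mean", "median")) {
  frequencies_mode <- match.arg(frequencies_mode)
  rate_mode <- match.arg(rate_mode)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (K < 1) stop("K must be >= 1")
  dat <- read_paml_dat(model_file(matrix_name))
  freq <- dat$freq
  if (frequencies_mode == "observed") {
    if (is.null(alignment)) stop("alignment required for observed frequencies")
    counts <- table(factor(alignment$matrix[alignment$matrix %in% AA20],
                           levels = AA20))
    if (sum(counts) == 0) stop("alignment contains no amino acids")
    freq <- as.numeric(counts) / sum(counts)
    names(freq) <- AA20
  }
  if (abs(sum(freq) - 1) > 1e-8) stop("frequencies do not sum to 1")
  model_from_parts(dat$S, freq, alpha, K, rate_mode, matrix_name)
}

# Assemble a substitution_model from exchangeabilities + frequencies; also
# the entry point for fully custom models in tests.
model_from_parts <- function(S, freq, alpha, K, rate_mode = "mean",
                             matrix_name = "custom") {
  # zero observed frequencies make the symmetrized generator singular;
  # floor them (the states become effectively unreachable, not impossible)
  if (any(freq <= 0)) {
    freq <- pmax(freq, 1e-10)
    freq <- freq / sum(freq)
  }
  Q <- S * rep(freq, each = 20)      # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q <- Q / scale
  # symmetrized eigendecomposition: B = D^{1/2} Q D^{-1/2} is symmetric
  sq <- sqrt(freq)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(
    name = matrix_name,
    S = S, freq = freq, Q = Q,
    alpha = alpha, K = as.integer(K),
    rates = discrete_gamma_rates(alpha, K, rate_mode),
    eigenvalues = eig$values,
    # P(t) = R diag(exp(lambda t)) Rinv with R = D^{-1/2} U
    right = (1 / sq) * eig$vectors,
    left = t(sq * eig$vectors)
  ), class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution_model: %s, alpha = %g, K = %d categories\n",
              x$name, x$alpha, x$K))
  invisible(x)
}

#' Discrete-gamma rate categories
#'
#' K equal-probability categories of a Gamma(shape = alpha, rate = alpha)
#' distribution (mean 1). With \code{rate_mode = "mean"} the category rate
#' is the conditional mean within each quantile bin, computed in closed form
#' via the incomplete-gamma identity
#' \eqn{E[X; X<q] = P(\alpha+1, \alpha q)} for Gamma(\eqn{\alpha,\alpha});
#' rates are renormalized to average exactly 1. With \code{"median"} the
#' bin medians are used (then renormalized likewise).
#'
#' @param alpha Gamma shape (> 0, finite).
#' @param K Number of categories (>= 1).
#' @param rate_mode \code{"mean"} or \code{"median"}.
#' @return Monotone increasing numeric vector of length K with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, K, rate_mode = c("mean", "median")) {
  rate_mode <- match.arg(rate_mode)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be finite and > 0")
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  if (rate_mode == "mean") {
    # mass of Gamma(alpha+1, alpha) below each bin edge; bin mean = K * diff
    cum <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
    rates <- K * diff(cum)
  } else {
    p <- (seq_len(K) - 0.5) / K
    rates <- stats::qgamma(p, shape = alpha, rate = alpha)
  }
  rates <- rates / mean(rates)
  rates
}

#' Transition probability matrix
#'
#' \eqn{P = \exp(Q t r)} via the precomputed eigendecomposition of the
#' symmetrized generator. Rows sum to 1; tiny negative entries from
#' round-off (>= -1e-12) are clamped to 0 and rows renormalized.
#'
#' @param model A \code{\link{build_model}} result.
#' @param t Branch length (>= 0), expected substitutions per site.
#' @param rate Rate multiplier (> 0), e.g. a gamma category rate.
#' @return 20x20 probability matrix (rows: from-state).
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  if (t == 0) return(diag(20))
  P <- model$right %*% (exp(model$eigenvalues * t * rate) * model$left)
  if (min(P) < -1e-12) {
    warning("transition matrix entries below tolerance; clamping")
  }
  P[P < 0] <- 0
  P / rowSums(P)
}
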