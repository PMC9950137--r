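# Synthetic-data generators with recorded ground truth. Sequence evolution
# follows the same model family the reconstruction engine assumes: a site's
# gamma rate category is drawn once and shared across the whole tree, and
# each branch evolves sites independently under P(Q t r). Indels are
# clade-restricted contiguous block deletions, inherited below the branch
# they occur on — enough to exercise the Fitch gap machinery.

#' Simulate an alignment along a tree
#'
#' The root sequence is drawn from the model's equilibrium frequencies;
#' each site is assigned one discrete-gamma category for the whole tree;
#' each branch substitutes states with transition matrix
#' \eqn{P(Q\,t\,r)}. \code{indel_spec} deletes contiguous column blocks on
#' named branches (identified by the child node's label or number); the
#' deletion is inherited by the entire clade below.
#'
#' @param tree Rooted \code{phylo} with branch lengths; leaves become the
#'   alignment rows.
#' @param model A \code{\link{build_model}} result.
#' @param n_sites Number of alignment columns (>= 1).
#' @param indel_spec Optional list of lists with fields \code{node} (child
#'   node of the branch on which the deletion happens) and \code{columns}
#'   (integer vector inside [1, n_sites]).
#' @param seed Integer seed; all randomness in the call derives from it.
#' @return List: \code{alignment} (\code{\link{aa_alignment}} of the
#'   leaves) and \code{truth} (class \code{simulation_truth}: per-node
#'   sequences, per-node presence masks, site categories, tree, seed).
#' @export
simulate_alignment <- function(tree, model, n_sites, indel_spec = NULL,
                               seed = 1) {
  validate_tree(tree)
  if (n_sites < 1) stop("n_sites must be >= 1")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  kids <- tree_children(tree)
  pe <- tree_parent_edge(tree)

  categories <- sample.int(model$K, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, nnode, n_sites)
  present <- matrix(TRUE, nnode, n_sites)
  states[root, ] <- sample.int(20, n_sites, replace = TRUE,
                               prob = model$freq)

  del_on <- vector("list", nnode)
  for (spec in indel_spec) {
    vid <- if (is.character(spec$node)) {
      if (spec$node %in% tree$tip.label) {
        match(spec$node, tree$tip.label)
      } else {
        internal_node_id(tree, spec$node)
      }
    } else {
      as.integer(spec$node)
    }
    cols <- as.integer(spec$columns)
    if (any(cols < 1 | cols > n_sites)) {
      stop("indel block outside [1, ", n_sites, "]")
    }
    del_on[[vid]] <- c(del_on[[vid]], cols)
  }

  Pk <- lapply(seq_len(model$K), function(k) NULL)  # per-edge cache unused; small trees
  # preorder traversal
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    for (c in kids[[v]]) {
      t <- pe$length[c]
      child_states <- states[v, ]
      for (k in unique(categories)) {
        P <- transition_matrix(model, t, model$rates[k])
        sel <- which(categories == k)
        for (s in sel) {
          child_states[s] <- sample.int(20, 1, prob = P[states[v, s], ])
        }
      }
      states[c, ] <- child_states
      present[c, ] <- present[v, ]
      if (length(del_on[[c]])) present[c, del_on[[c]]] <- FALSE
      stack <- c(stack, c)
    }
  }

  chars <- matrix(AA20[states], nnode, n_sites)
  chars[!present] <- GAP_CHAR
  leaf_mat <- chars[seq_len(ntip), , drop = FALSE]
  aln <- aa_alignment(tree$tip.label, leaf_mat)
  node_names <- c(tree$tip.label,
                  vapply(root:nnode, function(v) node_label_of(tree, v),
                         character(1)))
  rownames(chars) <- node_names
  rownames(present) <- node_names
  truth <- structure(list(sequences = chars, present = present,
                          categories = categories, tree = tree,
                          model_name = model$name, seed = seed),
                     class = "simulation_truth")
  list(alignment = aln, truth = truth)
}

# Gaussian-peak species spectrum on a wavelength grid.
gaussian_spectrum <- function(wavelength, center, width, height) {
  height * exp(-((wavelength - center)^2) / (2 * width^2))
}

#' Default species spectra for stopped-flow simulation
#'
#' Three Gaussian-peak spectra emulating the flavin species of the
#' oxidative half-reaction: reduced flavin (weak, broad, 360 nm), the
#' C4a-(hydro)peroxyflavin intermediate (380 nm) and oxidized flavin
#' (450 nm).
#'
#' @param wavelength Wavelength grid (nm).
#' @return Matrix wavelength x 3 (columns a, b, c).
#' @export
default_flavin_spectra <- function(wavelength) {
  cbind(a = gaussian_spectrum(wavelength, 360, 45, 0.012),
        b = gaussian_spectrum(wavelength, 380, 28, 0.055),
        c = gaussian_spectrum(wavelength, 450, 30, 0.090))
}

#' Simulate a stopped-flow photodiode-array matrix
#'
#' Closed-form a -> b -> c concentration profiles times Gaussian-peak
#' species spectra, plus i.i.d. Gaussian noise.
#'
#' @param k1,k2 Generating rate constants (s^-1).
#' @param time Time grid (s).
#' @param wavelength Wavelength grid (nm).
#' @param spectra Optional wavelength x 3 matrix; default
#'   \code{\link{default_flavin_spectra}}.
#' @param noise_sd Gaussian noise SD in absorbance units (>= 0).
#' @param seed Integer seed.
#' @return List: \code{time}, \code{wavelength}, \code{A} (time x
#'   wavelength), \code{truth} (generating parameters and spectra).
#' @export
simulate_stopped_flow <- function(k1, k2, time, wavelength,
                                  spectra = NULL, noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop("negative noise_sd")
  if (is.null(spectra)) spectra <- default_flavin_spectra(wavelength)
  set.seed(seed)
  C <- sequential_concentrations(time, k1, k2)
  A <- C %*% t(spectra)
  if (noise_sd > 0) {
    A <- A + matrix(stats::rnorm(length(A), 0, noise_sd),
                    nrow(A), ncol(A))
  }
  list(time = time, wavelength = wavelength, A = A,
       truth = list(k1 = k1, k2 = k2, spectra = spectra,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' \eqn{v = V_{max} S / (K_M + S)} with multiplicative Gaussian noise,
#' replicated over the concentration grid.
#'
#' @param K_M,V_max Generating parameters (> 0).
#' @param conc Concentration grid.
#' @param n_rep Replicates per concentration.
#' @param noise_frac SD of the multiplicative noise (e.g. 0.05 for 5%).
#' @param seed Integer seed.
#' @return data.frame: \code{conc}, \code{rate}, \code{replicate}; with
#'   attribute \code{truth}.
#' @export
simulate_initial_rates <- function(K_M, V_max, conc, n_rep = 3,
                                   noise_frac = 0.05, seed = 1) {
  if (K_M <= 0 || V_max <= 0) stop("parameters must be positive")
  set.seed(seed)
  S <- rep(conc, each = n_rep)
  v0 <- V_max * S / (K_M + S)
  v <- v0 * (1 + stats::rnorm(length(S), 0, noise_frac))
  out <- data.frame(conc = S, rate = v,
                    replicate = rep(seq_len(n_rep), times = length(conc)))
  attr(out, "truth") <- list(K_M = K_M, V_max = V_max,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Simulate a single-exponential trace
#'
#' \eqn{A(t) = A_\infty + (A_0 - A_\infty) e^{-kt}} plus Gaussian noise.
#'
#' @param k Rate constant (> 0, s^-1).
#' @param A0,A_inf Initial and final absorbance.
#' @param time Time grid (s).
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @return data.frame \code{time}, \code{absorbance}; attribute
#'   \code{truth}.
#' @export
simulate_trace_exponential <- function(k, A0, A_inf, time, noise_sd = 0,
                                       seed = 1) {
  if (k <= 0) stop("k must be positive")
  set.seed(seed)
  A <- A_inf + (A0 - A_inf) * exp(-k * time)
  if (noise_sd > 0) A <- A + stats::rnorm(length(time), 0, noise_sd)
  out <- data.frame(time = time, absorbance = A)
  attr(out, "truth") <- list(k = k, A0 = A0, A_inf = A_inf,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a thermal melt curve
#'
#' Logistic sigmoid centered at \code{T_m} with the stated slope, plus
#' noise; optionally a second transition.
#'
#' @param T_m Midpoint (degC).
#' @param slope Transition steepness (degC).
#' @param temperature Temperature grid.
#' @param amplitude Fluorescence amplitude.
#' @param second Optional list \code{(T_m, amplitude, slope)} for a second
#'   transition.
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @return data.frame \code{temperature}, \code{fluorescence}; attribute
#'   \code{truth}.
#' @export
simulate_melt_curve <- function(T_m, slope = 2, temperature = seq(25, 95, 0.5),
                                amplitude = 1, second = NULL, noise_sd = 0,
                                seed = 1) {
  set.seed(seed)
  f <- amplitude / (1 + exp(-(temperature - T_m) / slope))
  if (!is.null(second)) {
    f <- f + second$amplitude /
      (1 + exp(-(temperature - second$T_m) / second$slope))
  }
  if (noise_sd > 0) f <- f + stats::rnorm(length(temperature), 0, noise_sd)
  out <- data.frame(temperature = temperature, fluorescence = f)
  attr(out, "truth") <- list(T_m = T_m, slope = slope, second = second,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a conversion peak-area table
#'
#' Builds sample and control substrate/internal-standard area pairs with
#' stated depletion fractions.
#'
#' @param depletion_frac Fraction of substrate depleted per sample (in
#'   [0, 1]).
#' @param control_area Substrate peak area of the no-enzyme control.
#' @param is_area Internal-standard area (common scale).
#' @param noise_frac Multiplicative noise on areas.
#' @param seed Integer seed.
#' @return data.frame with per-sample areas and the control; attribute
#'   \code{truth}.
#' @export
simulate_conversion_table <- function(depletion_frac, control_area = 1e6,
                                      is_area = 2e5, noise_frac = 0,
                                      seed = 1) {
  if (any(depletion_frac < 0 | depletion_frac > 1)) {
    stop("depletion_frac must be in [0, 1]")
  }
  set.seed(seed)
  n <- length(depletion_frac)
  noise <- function(m) m * (1 + stats::rnorm(length(m), 0, noise_frac))
  out <- data.frame(
    sample = seq_len(n),
    substrate_area = noise(control_area * (1 - depletion_frac)),
    is_area = noise(rep(is_area, n)),
    control_substrate_area = rep(control_area, n),
    control_is_area = rep(is_area, n)
  )
  attr(out, "truth") <- list(depletion_frac = depletion_frac,
                             noise_frac = noise_frac, seed = seed)
  out
}
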