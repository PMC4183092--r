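#' Build the random balanced coupling matrix
#'
#' Wires a sparse signed coupling matrix with mean in-degree `kappa` from
#' each population: the first `ceiling((1 - frac_inhib) * N)` cells are
#' excitatory (non-negative outgoing weights), the rest inhibitory
#' (non-positive). Every ordered pair `(i, j != i)` with presynaptic cell
#' `j` in population `P` is connected independently with probability
#' `kappa / N_P`, and each realized edge has magnitude `4 / kappa`, which
#' gives the balanced-state scaling `|a_ij| ~ O(1/kappa)` (0.2 at
#' `kappa = 20`). Self-connections are excluded.
#'
#' @param cfg A [network_config()] object; the wiring uses
#'   `cfg$seeds$coupling`.
#' @return A `"coupling_matrix"`: a list with the sparse matrix `A`
#'   (`Matrix::dgCMatrix`, rows postsynaptic, columns presynaptic), the
#'   population label vector `populations` (`"E"`/`"I"`), and wiring
#'   metadata.
#' @examples
#' cfg <- network_config(N = 50, kappa = 4, master_seed = 7)
#' cm <- build_coupling_matrix(cfg)
#' range(cm$A@x)
#' @export
build_coupling_matrix <- function(cfg) {
  validate_config(cfg)
  N <- cfg$N
  n_exc <- ceiling((1 - cfg$frac_inhib) * N)
  pops <- rep(c("E", "I"), c(n_exc, N - n_exc))
  if (cfg$kappa == 0) {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(N, N))
  } else {
    n_pop <- c(E = n_exc, I = N - n_exc)
    p_col <- cfg$kappa / n_pop[pops] # connection probability per column
    if (any(p_col > 1)) {
      stop("invalid config: kappa/N_P > 1 for some population", call. = FALSE)
    }
    w <- 4 / cfg$kappa
    mask <- with_local_seed(cfg$seeds$coupling, {
      matrix(runif(N * N), N, N) < rep(p_col, each = N)
    })
    diag(mask) <- FALSE
    idx <- which(mask, arr.ind = TRUE)
    sgn <- ifelse(pops[idx[, 2]] == "E", w, -w)
    A <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = sgn,
                              dims = c(N, N))
  }
  structure(
    list(A = methods::as(A, "CsparseMatrix"), populations = pops,
         N = N, kappa = cfg$kappa, seed = cfg$seeds$coupling),
    class = "coupling_matrix"
  )
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf(
    "coupling matrix: N = %d, kappa = %g, %d edges (%d E / %d I cells)\n",
    x$N, x$kappa, length(x$A@x), sum(x$populations == "E"),
    sum(x$populations == "I")
  ))
  invisible(x)
}

#' Synaptic coupling pulse
#'
#' The smooth bump delivered by a presynaptic cell whose phase sits within
#' `b` of the spiking phase 1 ~ 0: `g(x) = (d/(2b)) * (1 - (x/b)^2)^3` for
#' `|x| <= b` and 0 outside. With the default `d = 35/32` the pulse
#' integrates to exactly 1/2 over its support, so a synapse of weight
#' `a_ij` delivers total phase charge `a_ij/4` per presynaptic spike (the
#' traversal speed at the spiking phase is 2). This scale is the one
#' consistent with the published firing-rate operating points of the
#' balanced network; see the methods vignette for the calibration argument.
#' The pulse is twice continuously differentiable at the support edges.
#'
#' @param x Centered phase offset(s), already reduced to
#'   `((theta + 1/2) %% 1) - 1/2`.
#' @param b Pulse half-width (default 1/20).
#' @param d Amplitude constant (default 35/32).
#' @return Pulse value(s), non-negative.
#' @export
coupling_pulse <- function(x, b = 1 / 20, d = 35 / 32) {
  out <- numeric(length(x))
  inside <- abs(x) <= b
  u <- x[inside] / b
  out[inside] <- (d / (2 * b)) * (1 - u^2)^3
  out
}

# centered representative of a phase: distance from the spiking phase 1 ~ 0
center_phase <- function(theta) ((theta + 0.5) %% 1) - 0.5

# derivative of the pulse with respect to phase
coupling_pulse_deriv <- function(x, b = 1 / 20, d = 35 / 32) {
  out <- numeric(length(x))
  inside <- abs(x) <= b
  u <- x[inside] / b
  out[inside] <- -3 * u * (d / b^2) * (1 - u^2)^2
  out
}

#' Drift vector field of the network
#'
#' Evaluates the deterministic drift of each neuron:
#' `F(theta_i) + Z(theta_i) * [sum_j a_ij g(theta_j) + (eps^2/2) Z'(theta_i)
#' + drive_i]`, with `F(theta) = 1 + cos(2*pi*theta)` and `Z(theta) = 1 -
#' cos(2*pi*theta)` in the normal variant. The per-neuron `drive` carries
#' the instantaneous external input (mean `eta` plus any fluctuation term);
#' the `eps^2/2` term is the Ito correction associated with the
#' multiplicative noise. In the piecewise variant `F` is constant 2 and `Z`
#' is 0 on the spiking interval `[1 - 2*dt_bin, 1)`.
#'
#' @param theta Phase vector on the N-torus, components in `[0, 1)`.
#' @param drive Per-neuron instantaneous input value (scalar recycled).
#' @param A A `"coupling_matrix"` or a plain matrix (use 0 for no coupling).
#' @param cfg A [network_config()].
#' @return The state derivative vector.
#' @export
vector_field <- function(theta, drive, A, cfg) {
  N <- length(theta)
  drive <- rep_len(drive, N)
  Amat <- if (inherits(A, "coupling_matrix")) A$A else A
  gvec <- coupling_pulse(center_phase(theta), cfg$b, cfg$d)
  coup <- as.numeric(Amat %*% gvec)
  co <- cos(2 * pi * theta)
  si <- sin(2 * pi * theta)
  F_ <- 1 + co
  Z_ <- 1 - co
  Zp <- 2 * pi * si
  if (cfg$model_variant == "piecewise") {
    g1 <- theta >= 1 - 2 * cfg$dt_bin
    F_[g1] <- 2
    Z_[g1] <- 0
    Zp[g1] <- 0
  }
  F_ + Z_ * (coup + (cfg$eps^2 / 2) * Zp + drive)
}

#' Analytic Jacobian of the drift vector field
#'
#' Dense Jacobian of [vector_field()] with respect to the phases: diagonal
#' terms from `F'`, `Z'` and the Ito correction, off-diagonal terms
#' `Z(theta_i) a_ij g'(theta_j)` from the coupling pulse. Used to
#' cross-check the tangent dynamics behind the Lyapunov computation against
#' finite differences.
#'
#' @inheritParams vector_field
#' @return An `N x N` matrix.
#' @export
vector_field_jacobian <- function(theta, drive, A, cfg) {
  N <- length(theta)
  drive <- rep_len(drive, N)
  Amat <- if (inherits(A, "coupling_matrix")) A$A else A
  Amat <- as.matrix(Amat)
  co <- cos(2 * pi * theta)
  si <- sin(2 * pi * theta)
  F_ <- 1 + co
  Fp <- -2 * pi * si
  Z_ <- 1 - co
  Zp <- 2 * pi * si
  Zpp <- (2 * pi)^2 * co
  gvec <- coupling_pulse(center_phase(theta), cfg$b, cfg$d)
  gp <- coupling_pulse_deriv(center_phase(theta), cfg$b, cfg$d)
  coup <- as.numeric(Amat %*% gvec)
  ito <- cfg$eps^2 / 2
  if (cfg$model_variant == "piecewise") {
    g1 <- theta >= 1 - 2 * cfg$dt_bin
    F_[g1] <- 2; Fp[g1] <- 0; Z_[g1] <- 0; Zp[g1] <- 0; Zpp[g1] <- 0
  }
  J <- sweep(Amat, 2, gp, `*`) * Z_ # Z_i * a_ij * g'(theta_j)
  diag(J) <- diag(J) + Fp + Zp * (coup + drive + ito * Zp) + Z_ * ito * Zpp
  J
}
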