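# Observables: undulation spectrum and its kappa/tau fit, reduced volume,
# and the DTS-unit to nanometre mapping.

#' Height-undulation spectrum of a framed membrane
#'
#' Computes `S(q) = A_p <|u_q|^2>` for the height field `u(r) = z - <z>`
#' over the reciprocal lattice of the (per-frame) box, averaged over
#' frames and binned by `|q|`; with this normalization a thermalized
#' membrane follows `S(q) = 1 / (kappa_eff q^4 + tau q^2)` in kBT units.
#'
#' Two estimators are provided. `"surface"` (the default) measures the
#' spectrum of the membrane surface itself: the piecewise-linear height
#' field of the triangulation is sampled on a regular oversampled grid and
#' Fourier-transformed, which is exact up to the (tiny) aliasing of the
#' interpolant and free of irregular-sampling leakage. `"vertex"`
#' estimates the amplitudes from the vertex heights alone by least-squares
#' regression on the plane-wave basis (the Lomb-Scargle approach to
#' unevenly sampled data): unbiased for heights sampled at points, but it
#' resolves the vertex field rather than the interpolated surface, whose
#' spectra differ near the lattice cutoff. See the methods vignette.
#'
#' @param frames list of frames `list(vertices, triangles, boxL)` as
#'   returned by [run_mc()], or a single [dts_mesh()].
#' @param method `"surface"` or `"vertex"` (see above).
#' @param modes maximum reciprocal-lattice index per axis; defaults to
#'   about the vertex Nyquist limit `floor(sqrt(N_v) / 2)`.
#' @param q_max maximum |q| retained. Defaults to 0.8 of the
#'   vertex-density Nyquist magnitude `pi * sqrt(N_v * sqrt(3)/2 / A_p)`;
#'   modes beyond the (hexagonal) Brillouin zone of a near-triangular
#'   vertex packing are not resolvable. For the `"vertex"` method the
#'   count of fitted amplitudes is additionally capped at `0.6 N_v` to
#'   keep the regression well-conditioned.
#' @param oversample grid oversampling factor of the `"surface"` method:
#'   the sampling grid has about `oversample * sqrt(N_v)` points per side.
#' @param bins number of |q| bins (default: up to 40 logarithmic bins).
#' @return An object of class `spectrum_result`: data.frame with columns
#'   `q`, `S`, `n_modes`, plus attributes `n_frames` and `A_p` (mean).
#' @export
undulation_spectrum <- function(frames, method = c("surface", "vertex"),
                                modes = NULL, q_max = NULL, oversample = 3,
                                bins = NULL) {
  method <- match.arg(method)
  if (inherits(frames, "dts_mesh"))
    frames <- list(list(vertices = frames$vertices, triangles = frames$triangles,
                        boxL = frames$box$L))
  if (length(frames) == 0) stop("no frames")
  nv <- nrow(frames[[1]]$vertices)
  if (is.null(modes)) modes <- max(2L, floor(sqrt(nv) / 2))
  L1 <- frames[[1]]$boxL
  if (is.null(q_max))
    q_max <- 0.8 * pi * sqrt(nv * sqrt(3) / 2 / (L1[1] * L1[2]))
  if (method == "surface" && is.null(frames[[1]]$triangles))
    stop("the surface estimator needs triangles in each frame")
  if (method == "vertex") {
    mg <- expand.grid(m = -modes:modes, n = 0:modes)
    mg <- mg[!(mg$n == 0 & mg$m <= 0), ] # half lattice; conjugate symmetry
    qm <- sqrt((2 * pi * mg$m / L1[1])^2 + (2 * pi * mg$n / L1[2])^2)
    mg <- mg[qm <= q_max * (1 + 1e-9), ]
    qm <- qm[qm <= q_max * (1 + 1e-9)]
    if (2 * nrow(mg) > 0.6 * nv) mg <- mg[order(qm)[seq_len(floor(0.3 * nv))], ]
    acc <- numeric(nrow(mg))
    qacc <- numeric(nrow(mg))
    Ap_sum <- 0
    for (fr in frames) {
      V <- fr$vertices
      L <- fr$boxL
      Ap <- L[1] * L[2]
      Ap_sum <- Ap_sum + Ap
      u <- V[, 3] - mean(V[, 3])
      qx <- 2 * pi * mg$m / L[1]
      qy <- 2 * pi * mg$n / L[2]
      phase <- outer(V[, 1], qx) + outer(V[, 2], qy) # nv x nq
      X <- cbind(cos(phase), -sin(phase))
      cf <- .lm.fit(X, u)$coefficients # (2 a_q, 2 b_q)
      nq <- nrow(mg)
      acc <- acc + Ap * (cf[1:nq]^2 + cf[(nq + 1):(2 * nq)]^2) / 4
      qacc <- qacc + sqrt(qx^2 + qy^2)
    }
    S <- acc / length(frames)
    qmag <- qacc / length(frames)
    wt <- rep(1, length(S))
  } else {
    ng <- 2^ceiling(log2(oversample * sqrt(nv)))
    mm <- c(0:(ng / 2), -((ng / 2 - 1):1))
    qsel <- NULL
    acc <- NULL
    qacc <- NULL
    Ap_sum <- 0
    for (fr in frames) {
      L <- fr$boxL
      Ap <- L[1] * L[2]
      Ap_sum <- Ap_sum + Ap
      z <- cpp_sample_heights(fr$vertices, fr$triangles, L, ng)
      u <- z - mean(z)
      U <- stats::fft(u) / ng^2
      qx <- 2 * pi * outer(mm, rep(1, ng)) / L[1]
      qy <- 2 * pi * outer(rep(1, ng), mm) / L[2]
      q <- sqrt(qx^2 + qy^2)
      if (is.null(qsel)) {
        # keep the half lattice (conjugate symmetry) within the cap
        half <- outer(mm, rep(1, ng), function(a, b) a) > 0 |
          (outer(mm, rep(1, ng), function(a, b) a) == 0 &
             outer(rep(1, ng), mm, function(a, b) b) > 0)
        qsel <- which(half & q > 0 & q <= q_max * (1 + 1e-9))
        acc <- numeric(length(qsel))
        qacc <- numeric(length(qsel))
      }
      acc <- acc + Ap * Mod(U[qsel])^2
      qacc <- qacc + q[qsel]
    }
    S <- acc / length(frames)
    qmag <- qacc / length(frames)
    wt <- rep(1, length(S))
  }
  if (is.null(bins)) bins <- min(40L, length(unique(round(qmag, 8))))
  br <- exp(seq(log(min(qmag) * 0.999), log(max(qmag) * 1.001), length.out = bins + 1))
  bi <- cut(qmag, br, include.lowest = TRUE)
  out <- data.frame(
    q = as.numeric(tapply(qmag, bi, mean)),
    S = as.numeric(tapply(S, bi, mean)),
    n_modes = as.integer(tapply(S, bi, length)))
  out <- out[!is.na(out$q), ]
  rownames(out) <- NULL
  structure(out, class = c("spectrum_result", "data.frame"),
            n_frames = length(frames), A_p = Ap_sum / length(frames))
}

#' Fit bending rigidity and tension to an undulation spectrum
#'
#' Least-squares fit of `1/S` against `(q^4, q^2)` giving the effective
#' (renormalized) bending rigidity `kappa_eff >= 0` and the frame tension
#' `tau` (unconstrained in sign), plus the log-log slope of `S(q)` over the
#' fit window. A tensionless membrane shows slope -4 at large `q`; under
#' tension the small-`q` slope approaches -2.
#'
#' @param spec a [undulation_spectrum()] result (or data.frame with `q`, `S`).
#' @param window optional `c(qmin, qmax)` restricting the fit; default all
#'   bins.
#' @return A list with `kappa_eff`, `tau`, `slope`, `residual` (rms of the
#'   relative fit error) and the number of bins used.
#' @export
fit_spectrum <- function(spec, window = NULL) {
  q <- spec$q
  S <- spec$S
  keep <- S > 0
  if (!is.null(window)) keep <- keep & q >= window[1] & q <= window[2]
  q <- q[keep]; S <- S[keep]
  if (length(q) < 4) stop("need at least 4 spectrum bins in the fit window")
  n <- if (!is.null(spec$n_modes)) spec$n_modes[keep] else rep(1, length(q))
  y <- 1 / S
  # inverse-variance weights: sd(1/S) is proportional to (1/S)/sqrt(n)
  w <- n * S^2
  fit <- lm(y ~ 0 + I(q^4) + I(q^2), weights = w)
  kap <- unname(coef(fit)[1])
  tau <- unname(coef(fit)[2])
  if (kap < 0) { # nonnegativity on kappa_eff: refit tension-only
    kap <- 0
    tau <- unname(coef(lm(y ~ 0 + I(q^2), weights = w))[1])
  }
  sl <- unname(coef(lm(log(S) ~ log(q)))[2])
  pred <- kap * q^4 + tau * q^2
  list(kappa_eff = kap, tau = tau, slope = sl,
       residual = sqrt(mean((1 - pred / y)^2)), n_bins = length(q))
}

#' Log-log slope of the spectrum over the upper half of resolved q
#'
#' The default large-`q` scaling diagnostic: a straight-line fit of
#' `log S` versus `log q` for bins with `q` above half the maximum
#' resolved magnitude.
#'
#' @param spec a [undulation_spectrum()] result.
#' @param fraction lower edge of the window as a fraction of `max(q)`.
#' @return The fitted slope.
#' @export
spectrum_large_q_slope <- function(spec, fraction = 0.5) {
  keep <- spec$q >= fraction * max(spec$q) & spec$S > 0
  if (sum(keep) < 3) stop("too few bins in the large-q window")
  unname(coef(lm(log(spec$S[keep]) ~ log(spec$q[keep])))[2])
}

#' Synthetic spectrum frames drawn from the continuum undulation model
#'
#' Generates independent Gaussian-mode height fields on the vertices of a
#' framed mesh with the exact covariance
#' `<|u_q|^2> = 1 / (A_p (kappa q^4 + tau q^2))`, for validating the
#' spectrum estimator and fit without running Monte Carlo.
#'
#' @param mesh a framed (x,y-periodic) [dts_mesh()].
#' @param kappa,tau model parameters of the generated spectrum.
#' @param n_frames number of independent frames.
#' @param modes maximum lattice index per axis.
#' @return A list of frames compatible with [undulation_spectrum()].
#' @export
synthetic_spectrum_frames <- function(mesh, kappa = 20, tau = 0,
                                      n_frames = 100, modes = NULL) {
  L <- mesh$box$L
  if (!all(mesh$box$periodic[1:2])) stop("framed mesh required")
  nv <- nrow(mesh$vertices)
  if (is.null(modes)) modes <- max(2L, floor(sqrt(nv) / 2))
  mg <- expand.grid(m = -modes:modes, n = 0:modes)
  mg <- mg[!(mg$n == 0 & mg$m <= 0), ]
  qx <- 2 * pi * mg$m / L[1]
  qy <- 2 * pi * mg$n / L[2]
  q2 <- qx^2 + qy^2
  keep <- sqrt(q2) <= pi * sqrt(nv * sqrt(3) / 2 / (L[1] * L[2])) * (1 + 1e-9)
  mg <- mg[keep, ]; qx <- qx[keep]; qy <- qy[keep]; q2 <- q2[keep]
  Ap <- L[1] * L[2]
  sig2 <- 1 / (Ap * (kappa * q2^2 + tau * q2))
  phase <- outer(mesh$vertices[, 1], qx) + outer(mesh$vertices[, 2], qy)
  cp <- cos(phase); sp <- sin(phase)
  lapply(seq_len(n_frames), function(k) {
    a <- rnorm(length(q2), sd = sqrt(sig2 / 2))
    b <- rnorm(length(q2), sd = sqrt(sig2 / 2))
    # u_j = sum_q 2 Re(u_q e^{i q r_j}) over the half lattice
    u <- 2 * (cp %*% a - sp %*% b)
    V <- mesh$vertices
    V[, 3] <- u
    list(vertices = V, triangles = mesh$triangles, boxL = L)
  })
}

#' Reduced volume of a closed mesh
#'
#' `v = V / (A^{3/2} / (6 sqrt(pi)))`: the enclosed volume divided by the
#' volume of the sphere with the same area. Equals 1 for a perfect sphere
#' and is smaller for any other shape.
#'
#' @param mesh a closed [dts_mesh()].
#' @return The reduced volume.
#' @export
reduced_volume <- function(mesh) {
  V <- enclosed_volume(mesh)
  A <- sum(triangle_geometry(mesh)$area)
  V / (A^1.5 / (6 * sqrt(pi)))
}

#' Map the DTS length unit to nanometres from a protein's lateral size
#'
#' A vertex is the interaction patch of one inclusion, so the protein
#' cross-section `pi (d/2)^2` is equated with the minimal per-vertex patch
#' area `(sqrt(3)/2) l^2` of a unit-edge triangulated surface, giving the
#' physical size of one DTS length unit
#' `l = (d/2) sqrt(2 pi / sqrt(3))`. A 7.2 nm protein (cholera/Shiga toxin
#' B subunit) gives `l ~ 6.9` nm, so a model curvature of 0.4 per DTS unit
#' is about 0.058 per nm.
#'
#' @param protein_size_nm lateral protein diameter in nm (> 0).
#' @return A list with `l_dts_nm` and converter functions
#'   `curvature_to_nm(c)` (1/l_dts -> 1/nm) and `area_to_nm2(a)`.
#' @export
length_mapping <- function(protein_size_nm) {
  if (protein_size_nm <= 0) stop("protein size must be positive")
  l <- (protein_size_nm / 2) * sqrt(2 * pi / sqrt(3))
  list(l_dts_nm = l,
       curvature_to_nm = function(c) c / l,
       area_to_nm2 = function(a) a * l^2)
}
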