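# Range-separation-parameter tuning for long-range-corrected functionals:
# the J^2(mu) Koopmans-residual objective, curve assembly from per-mu
# species energies, natural-cubic-spline interpolation of missing points,
# and spline-based minimization.

#' Koopmans-residual tuning objective
#'
#' `J^2(mu) = [E_HOMO(N) + IP(N)]^2 + [E_HOMO(N+1) + IP(N+1)]^2`: the
#' squared deviations from Koopmans' condition for the N- and
#' (N+1)-electron systems. An optimally tuned range-separation parameter
#' minimizes this over mu.
#'
#' @param e_homo_n,ip_n HOMO energy and IP of the N-electron system,
#'   kcal/mol.
#' @param e_homo_n1,ip_n1 same for the (N+1)-electron (anion) system.
#' @return J^2 in kcal^2/mol^2 (>= 0).
#' @export
j_squared <- function(e_homo_n, ip_n, e_homo_n1, ip_n1) {
  (e_homo_n + ip_n)^2 + (e_homo_n1 + ip_n1)^2
}

#' Build a tuning curve from per-mu species triples
#'
#' Each entry supplies the neutral, cation and anion of one compound at
#' one value of the range-separation parameter mu. Vertical ionization
#' potentials are taken as energy differences,
#' `IP(N) = E(cation) - E(neutral)` and `IP(N+1) = E(neutral) - E(anion)`,
#' and combined with the neutral's and anion's HOMO energies into the
#' J^2 objective. Points are sorted by mu.
#'
#' @param per_mu_records list of lists with elements `mu`, `neutral`,
#'   `cation`, `anion` (the latter three `species_record`s with charges
#'   q, q+1, q-1 respectively; `neutral` and `anion` must carry `e_homo`).
#' @return object of class `tuning_curve`: a data frame with columns
#'   `mu`, `e_homo_n`, `e_homo_n1`, `ip_n`, `ip_n1`, `j2`, `interpolated`.
#' @export
build_curve <- function(per_mu_records) {
  if (length(per_mu_records) == 0) {
    stop("empty input: a tuning curve needs at least 4 points", call. = FALSE)
  }
  rows <- lapply(per_mu_records, function(e) {
    q <- e$neutral$charge
    if (e$cation$charge != q + 1L || e$anion$charge != q - 1L) {
      stop("charge pattern at mu = ", e$mu, " must be (q, q+1, q-1), got (",
           q, ", ", e$cation$charge, ", ", e$anion$charge, ")", call. = FALSE)
    }
    if (is.null(e$neutral$e_homo) || is.null(e$anion$e_homo)) {
      stop("neutral and anion records at mu = ", e$mu,
           " must carry e_homo", call. = FALSE)
    }
    ip_n <- e$cation$energy - e$neutral$energy
    ip_n1 <- e$neutral$energy - e$anion$energy
    data.frame(mu = e$mu, e_homo_n = e$neutral$e_homo,
               e_homo_n1 = e$anion$e_homo, ip_n = ip_n, ip_n1 = ip_n1,
               j2 = j_squared(e$neutral$e_homo, ip_n, e$anion$e_homo, ip_n1),
               interpolated = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$mu), , drop = FALSE]
  if (anyDuplicated(df$mu)) stop("duplicate mu values", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("tuning_curve", "data.frame")
  df
}

#' Construct a tuning curve directly from (mu, J^2) pairs
#'
#' For workflows where only the objective values are available (e.g. read
#' from a table) rather than the underlying species energies.
#'
#' @param mu,j2 numeric vectors of equal length.
#' @return a `tuning_curve`.
#' @export
tuning_curve_from_j2 <- function(mu, j2) {
  stopifnot(length(mu) == length(j2))
  if (any(j2 < 0)) stop("J^2 values must be >= 0", call. = FALSE)
  df <- data.frame(mu = mu, e_homo_n = NA_real_, e_homo_n1 = NA_real_,
                   ip_n = NA_real_, ip_n1 = NA_real_, j2 = j2,
                   interpolated = FALSE)
  df <- df[order(df$mu), , drop = FALSE]
  if (anyDuplicated(df$mu)) stop("duplicate mu values", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("tuning_curve", "data.frame")
  df
}

curve_spline <- function(curve) {
  known <- curve[!curve$interpolated, , drop = FALSE]
  if (nrow(known) < 4) {
    stop("at least 4 directly computed points are required for spline work",
         call. = FALSE)
  }
  splinefun(known$mu, known$j2, method = "natural")
}

#' Fill missing tuning-curve points by spline interpolation
#'
#' When the underlying self-consistent-field calculation fails to converge
#' at particular mu values, the corresponding J^2 points are recovered by
#' natural-cubic-spline interpolation of the converged points. Filled
#' points are flagged `interpolated = TRUE`; known points are never
#' altered. Extrapolation outside the known mu range is refused.
#'
#' @param curve a `tuning_curve`.
#' @param missing_mus mu values to fill, strictly inside the known range.
#' @return the augmented `tuning_curve`.
#' @export
interpolate_missing <- function(curve, missing_mus) {
  sp <- curve_spline(curve)
  known <- curve[!curve$interpolated, , drop = FALSE]
  rng <- range(known$mu)
  if (any(missing_mus < rng[1] | missing_mus > rng[2])) {
    stop("requested mu outside the known range [", rng[1], ", ", rng[2],
         "]: refusing to extrapolate", call. = FALSE)
  }
  add <- data.frame(mu = missing_mus, e_homo_n = NA_real_, e_homo_n1 = NA_real_,
                    ip_n = NA_real_, ip_n1 = NA_real_,
                    j2 = pmax(sp(missing_mus), 0), interpolated = TRUE)
  out <- rbind(as.data.frame(curve), add)
  out <- out[order(out$mu), , drop = FALSE]
  if (anyDuplicated(out$mu)) {
    stop("requested mu coincides with an existing point", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("tuning_curve", "data.frame")
  out
}

#' Locate the optimal range-separation parameter
#'
#' Minimizes the natural-cubic-spline interpolant of the J^2 curve over
#' the full mu range: a dense scan at 1e-4 resolution brackets the global
#' minimum, which golden-section search then refines to 1e-6. Ties are
#' broken toward smaller mu.
#'
#' @param curve a `tuning_curve` with at least 4 directly computed points.
#' @return the minimizing mu (dimensionless).
#' @export
find_optimal_mu <- function(curve) {
  sp <- curve_spline(curve)
  known <- curve[!curve$interpolated, , drop = FALSE]
  rng <- range(known$mu)
  grid <- seq(rng[1], rng[2], by = 1e-4)
  vals <- sp(grid)
  best <- which(vals <= min(vals) + .Machine$double.eps * abs(min(vals)))[1]
  if (best == 1L || best == length(grid)) {
    # boundary minimum: no interior bracket to refine
    return(grid[best])
  }
  opt <- optimize(sp, lower = grid[best - 1L], upper = grid[best + 1L],
                  tol = 1e-6)
  if (opt$objective <= vals[best]) opt$minimum else grid[best]
}
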