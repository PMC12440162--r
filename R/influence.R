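#' Fit a vector autoregressive (VAR) model by conditional least squares
#'
#' Fits \eqn{y_t = \sum_{m=1}^p A_m y_{t-m} + w_t} to a multivariate series
#' after removing the sample mean of each channel. Coefficients are estimated
#' equation-by-equation by ordinary least squares conditional on the first
#' \eqn{p} observations; the innovation covariance is the residual
#' cross-product divided by \eqn{n_{used} - kp} (observations actually
#' regressed minus regressors per equation), the small-sample correction used
#' throughout this package.
#'
#' When \code{order = "auto"} the order is chosen by minimising an information
#' criterion over \code{1:p_max}, with all candidate orders scored on the same
#' effective sample (the last \eqn{n - p_{max}} observations) so their
#' likelihoods are comparable; the winning order is then refit on its full
#' conditional sample.
#'
#' @param y numeric matrix, one column per channel, one row per time point.
#' @param order integer VAR order, or \code{"auto"}.
#' @param p_max maximum order considered when \code{order = "auto"}.
#' @param ic information criterion for automatic order selection,
#'   \code{"aic"} or \code{"bic"}.
#' @return an object of class \code{"var_model"}: a list with elements
#'   \code{p}, \code{A} (list of k-by-k coefficient matrices),
#'   \code{Sigma} (innovation covariance), \code{n_obs}, \code{n_used},
#'   \code{k}, \code{ic_table}.
#' @examples
#' y <- simulate_var(list(matrix(c(0.5, 0.3, 0, 0.5), 2)), diag(2), 500, seed = 1)
#' fit_var(y, order = 1)$A[[1]]
#' @export
fit_var <- function(y, order = "auto", p_max = 3L, ic = c("aic", "bic")) {
  ic <- match.arg(ic)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (anyNA(y) || any(!is.finite(y))) stop("series contains non-finite values")
  n <- nrow(y)
  k <- ncol(y)
  if (any(apply(y, 2, stats::sd) == 0))
    stop("constant channel: VAR regression is singular")
  yc <- sweep(y, 2, colMeans(y))

  fit_p <- function(p, offset) {
    # offset: first usable response index minus 1 (>= p)
    idx <- seq.int(offset + 1L, n)
    n_used <- length(idx)
    if (n_used <= k * p)
      stop("series too short for VAR order ", p)
    X <- do.call(cbind, lapply(seq_len(p), function(m) yc[idx - m, , drop = FALSE]))
    Y <- yc[idx, , drop = FALSE]
    B <- tryCatch(qr.solve(X, Y), error = function(e)
      stop("singular VAR regression (degenerate series)", call. = FALSE))
    res <- Y - X %*% B
    dof <- n_used - k * p
    if (dof < 1) stop("series too short for VAR order ", p)
    Sigma <- crossprod(res) / dof
    list(p = p, B = B, Sigma = Sigma, res = res, n_used = n_used)
  }

  if (identical(order, "auto")) {
    if (n <= p_max + k * p_max) p_max <- max(1L, (n - 1L) %/% (k + 1L))
    scores <- vapply(seq_len(p_max), function(p) {
      f <- fit_p(p, p_max)                      # common sample for comparability
      S <- crossprod(f$res) / f$n_used          # ML covariance for the criterion
      ld <- determinant(S, logarithm = TRUE)$modulus
      pen <- if (ic == "aic") 2 else log(f$n_used)
      as.numeric(f$n_used * ld + pen * (k * k * p))
    }, numeric(1))
    p <- which.min(scores)
    ic_table <- data.frame(p = seq_len(p_max), score = scores)
  } else {
    p <- as.integer(order)
    if (p < 1) stop("order must be >= 1")
    ic_table <- NULL
  }
  f <- fit_p(p, p)
  A <- lapply(seq_len(p), function(m)
    t(f$B[(m - 1L) * k + seq_len(k), , drop = FALSE]))
  structure(list(p = p, A = A, Sigma = f$Sigma, n_obs = n, n_used = f$n_used,
                 k = k, ic_table = ic_table),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("VAR(", x$p, ") model, ", x$k, " channels, n_obs = ", x$n_obs, "\n", sep = "")
  for (m in seq_len(x$p)) {
    cat("A_", m, ":\n", sep = "")
    print(round(x$A[[m]], 4))
  }
  cat("innovation covariance:\n")
  print(round(x$Sigma, 4))
  invisible(x)
}

#' Partial directed coherence spectra from a fitted VAR model
#'
#' Evaluates, on a uniform frequency grid over \eqn{[0, fs/2]}, the squared
#' magnitude of a partial-directed-coherence statistic for every ordered
#' channel pair \eqn{j \to i}. Writing
#' \eqn{\bar A(f) = I - \sum_m A_m e^{-i 2\pi f m / fs}} with columns
#' \eqn{\bar a_j(f)}, the variants are:
#' \describe{
#'   \item{\code{ipdc}}{information PDC,
#'     \eqn{|\bar A_{ij}|^2 / (\sigma_{ii} \, \bar a_j^H \Sigma_w^{-1} \bar a_j)}
#'     with \eqn{\sigma_{ii} = [\Sigma_w]_{ii}}; its integrand
#'     \eqn{-\log_2(1 - \mathrm{iPDC})} is a mutual-information-rate density,
#'     and it is bounded in \eqn{[0, 1]} for any positive-definite
#'     \eqn{\Sigma_w}.}
#'   \item{\code{gpdc}}{generalized PDC,
#'     \eqn{(|\bar A_{ij}|^2/\sigma_{ii}) / \sum_k |\bar A_{kj}|^2/\sigma_{kk}};
#'     equals \code{ipdc} when \eqn{\Sigma_w} is diagonal.}
#'   \item{\code{pdc}}{classic PDC, column-norm normalization
#'     \eqn{|\bar A_{ij}|^2 / \sum_k |\bar A_{kj}|^2}; sums to 1 over targets
#'     \eqn{i} for each source \eqn{j}.}
#' }
#'
#' @param model a \code{"var_model"}.
#' @param n_freqs number of grid points (inclusive of both endpoints).
#' @param fs sampling rate (frames per second).
#' @param variant which normalization to use; \code{"ipdc"} is the default.
#' @return an object of class \code{"ipdc_spectrum"}: list with \code{freqs}
#'   (length \code{n_freqs}), \code{values} (array
#'   \code{n_freqs x k x k}; \code{values[f, i, j]} is direction j to i;
#'   diagonal slices are \code{NA}), \code{fs}, \code{variant}.
#' @export
ipdc_spectrum <- function(model, n_freqs = 128L, fs = 1,
                          variant = c("ipdc", "gpdc", "pdc")) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "var_model"), n_freqs >= 2, fs > 0)
  k <- model$k
  Sigma <- model$Sigma
  if (variant != "pdc") {
    Sinv <- tryCatch(solve(Sigma), error = function(e)
      stop("singular innovation covariance", call. = FALSE))
    sii <- diag(Sigma)
    if (any(sii <= 0)) stop("singular innovation covariance")
  }
  freqs <- seq(0, fs / 2, length.out = n_freqs)
  vals <- array(NA_real_, dim = c(n_freqs, k, k))
  for (fi in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[fi] * seq_len(model$p) / fs)
    Abar <- diag(k) + 0i
    for (m in seq_len(model$p)) Abar <- Abar - model$A[[m]] * z[m]
    for (j in seq_len(k)) {
      aj <- Abar[, j]
      num <- Mod(aj)^2
      vals[fi, , j] <- switch(variant,
        ipdc = num / (diag(Sigma) * Re(Conj(aj) %*% Sinv %*% aj)[1]),
        gpdc = (num / sii) / sum(num / sii),
        pdc  = num / sum(num))
    }
  }
  for (i in seq_len(k)) vals[, i, i] <- NA_real_
  structure(list(freqs = freqs, values = vals, fs = fs, variant = variant,
                 k = k),
            class = "ipdc_spectrum")
}

#' @export
print.ipdc_spectrum <- function(x, ...) {
  cat(toupper(x$variant), " spectrum: ", length(x$freqs), " frequencies on [0, ",
      x$fs / 2, "], ", x$k, " channels\n", sep = "")
  invisible(x)
}

#' Extract one direction of a PDC spectrum as a numeric vector
#'
#' @param spectrum an \code{"ipdc_spectrum"}.
#' @param from source channel index.
#' @param to target channel index.
#' @return numeric vector over the frequency grid.
#' @export
spectrum_direction <- function(spectrum, from, to) {
  stopifnot(inherits(spectrum, "ipdc_spectrum"), from != to)
  spectrum$values[, to, from]
}

#' Integrate a coherence spectrum into information flow (bits)
#'
#' Computes \deqn{I_{flow} = -\frac{1}{fs}\int_0^{fs/2} \log_2(1 - iPDC(f))\,df}
#' by the trapezoidal rule on the spectrum's own grid. Values are clipped to
#' \code{1 - clip_eps} before the logarithm as a floating-point guard; a value
#' at or above 1 beyond that window is an invalid spectrum and raises an error.
#'
#' @param spectrum an \code{"ipdc_spectrum"} or a bare numeric vector of
#'   squared-coherence values (then \code{freqs}/\code{fs} must be given).
#' @param from,to ordered direction (channel indices) when \code{spectrum} is
#'   an \code{"ipdc_spectrum"}.
#' @param freqs,fs frequency grid and sampling rate for the vector form.
#' @param clip_eps boundary clipping window.
#' @return non-negative information flow in bits.
#' @examples
#' f <- seq(0, 0.5, length.out = 128)
#' information_flow(rep(0.5, 128), freqs = f, fs = 1)  # 0.5 bits
#' @export
information_flow <- function(spectrum, from = 1L, to = 2L,
                             freqs = NULL, fs = NULL, clip_eps = 1e-12) {
  if (inherits(spectrum, "ipdc_spectrum")) {
    v <- spectrum_direction(spectrum, from, to)
    freqs <- spectrum$freqs
    fs <- spectrum$fs
  } else {
    v <- as.numeric(spectrum)
    if (is.null(freqs) || is.null(fs))
      stop("freqs and fs are required for a bare spectrum vector")
  }
  if (anyNA(v)) stop("spectrum contains NA values")
  if (any(v < 0)) stop("invalid spectrum: negative values")
  if (any(v >= 1 + clip_eps)) stop("invalid spectrum: values >= 1")
  v <- pmin(v, 1 - clip_eps)
  g <- -log2(1 - v)
  sum(diff(freqs) * (g[-1] + g[-length(g)]) / 2) / fs
}

#' Per-bee social influence from proximal-interaction windows
#'
#' For one focal bee: per axis (X, Y) and per proximity interaction, fits a
#' bivariate VAR to the (focal, neighbor) coordinate series, computes the
#' iPDC spectrum in both directions on a shared frequency grid, averages the
#' spectra pointwise across interactions per axis, integrates the averaged
#' spectra into information flow per direction per axis, and finally averages
#' the X and Y flows. This follows the averaging order of the original
#' analysis: spectra first, then the integral, then the two coordinate axes.
#'
#' @param traj a trajectory table (see \code{\link{simulate_trajectories}}).
#' @param interactions interaction index table from
#'   \code{\link{find_proximity_interactions}}.
#' @param focal_id the focal bee.
#' @param settings an \code{\link{influence_settings}} list.
#' @return one-row data.frame: \code{bee_id}, \code{i_flow_out} (focal to
#'   neighbor, bits), \code{i_flow_in}, per-axis components
#'   (\code{i_out_x}, \code{i_out_y}, \code{i_in_x}, \code{i_in_y}),
#'   \code{n_interactions}, \code{n_failed}. All-NA flows with a warning when
#'   every interaction failed to fit.
#' @export
social_influence <- function(traj, interactions, focal_id,
                             settings = influence_settings()) {
  ints <- interactions[interactions$focal_id == focal_id, , drop = FALSE]
  if (nrow(ints) == 0) stop("no interactions for focal bee ", focal_id)
  fs <- attr(traj, "fs") %||% settings$fs
  n_freqs <- settings$n_freqs
  acc <- list(X = list(out = NULL, inn = NULL), Y = list(out = NULL, inn = NULL))
  n_ok <- 0L
  for (r in seq_len(nrow(ints))) {
    specs <- tryCatch({
      lapply(c(X = "X", Y = "Y"), function(ax) {
        s <- build_bivariate_series(traj, ints$focal_id[r], ints$neighbor_id[r],
                                    ints$start_frame[r], ints$end_frame[r], ax)
        m <- fit_var(s, order = settings$order, p_max = settings$p_max)
        sp <- ipdc_spectrum(m, n_freqs = n_freqs, fs = fs,
                            variant = settings$variant)
        list(out = spectrum_direction(sp, 1, 2),
             inn = spectrum_direction(sp, 2, 1))
      })
    }, error = function(e) NULL)
    if (is.null(specs)) next
    n_ok <- n_ok + 1L
    for (ax in c("X", "Y")) for (d in c("out", "inn")) {
      cur <- acc[[ax]][[d]]
      acc[[ax]][[d]] <- if (is.null(cur)) specs[[ax]][[d]] else cur + specs[[ax]][[d]]
    }
  }
  if (n_ok == 0L) {
    warning("all ", nrow(ints), " interactions failed to fit for bee ", focal_id)
    return(data.frame(bee_id = focal_id, i_flow_out = NA_real_,
                      i_flow_in = NA_real_, i_out_x = NA_real_,
                      i_out_y = NA_real_, i_in_x = NA_real_, i_in_y = NA_real_,
                      n_interactions = nrow(ints), n_failed = nrow(ints)))
  }
  freqs <- seq(0, fs / 2, length.out = n_freqs)
  flow <- function(ax, d)
    information_flow(acc[[ax]][[d]] / n_ok, freqs = freqs, fs = fs)
  i_out_x <- flow("X", "out"); i_out_y <- flow("Y", "out")
  i_in_x <- flow("X", "inn"); i_in_y <- flow("Y", "inn")
  data.frame(bee_id = focal_id,
             i_flow_out = (i_out_x + i_out_y) / 2,
             i_flow_in = (i_in_x + i_in_y) / 2,
             i_out_x = i_out_x, i_out_y = i_out_y,
             i_in_x = i_in_x, i_in_y = i_in_y,
             n_interactions = nrow(ints),
             n_failed = nrow(ints) - n_ok)
}

#' Settings for the social-influence estimator
#'
#' @param order VAR order policy: \code{"auto"} or a fixed integer.
#' @param p_max maximum order under automatic selection; the default cap of 3
#'   keeps the parameter count (12) well below a 30-sample window.
#' @param n_freqs frequency-grid size on \eqn{[0, fs/2]}.
#' @param variant PDC normalization (see \code{\link{ipdc_spectrum}}).
#' @param fs fallback sampling rate when the trajectory carries none.
#' @return a list of settings.
#' @export
influence_settings <- function(order = "auto", p_max = 3L, n_freqs = 128L,
                               variant = "ipdc", fs = 1) {
  list(order = order, p_max = p_max, n_freqs = n_freqs, variant = variant,
       fs = fs)
}

#' Social influence for every focal bee with at least one interaction
#'
#' @inheritParams social_influence
#' @return data.frame with one row per focal bee (see
#'   \code{\link{social_influence}}).
#' @export
social_influence_all <- function(traj, interactions,
                                 settings = influence_settings()) {
  focals <- unique(interactions$focal_id)
  do.call(rbind, lapply(focals, function(b)
    social_influence(traj, interactions, b, settings)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
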