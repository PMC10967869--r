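# Model-based full-factorial DoE, quadratic response-surface regression and
# analytic optimal-setpoint calculation.
#
# Factors (declaration order): initial permeate setpoint Q_set [L/h], feed
# concentration c_feed [g/L], reference steady-state cake resistance
# Rcake_SS_ref [m^-1]. Factors are min-max scaled to [0, 1] before the fit
# because their magnitudes differ by ~11 orders. The response (productivity,
# L/h) is left unscaled.

#' Design space of the in-silico experiments
#'
#' @param q_set_lph numeric length-2 bounds of the initial permeate setpoint.
#' @param c_feed_gpl bounds of the feed concentration.
#' @param rcake_ss_ref_per_m bounds of the reference steady-state cake
#'   resistance.
#' @param n_levels number of evenly spaced levels per factor (>= 2).
#' @param duration_h duration of every in-silico run.
#' @return an object of class `dcf_design`.
#' @export
dcf_design_space <- function(q_set_lph = c(400, 1200),
                             c_feed_gpl = c(20, 100),
                             rcake_ss_ref_per_m = c(6e12, 2.2e13),
                             n_levels = 5L,
                             duration_h = 10) {
  bounds <- list(q_set_lph = q_set_lph, c_feed_gpl = c_feed_gpl,
                 rcake_ss_ref_per_m = rcake_ss_ref_per_m)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (!is.numeric(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("dcf_design_space: ", nm, " must be finite bounds with low < high",
           call. = FALSE)
  }
  if (n_levels < 2) stop("dcf_design_space: n_levels must be >= 2",
                         call. = FALSE)
  structure(c(bounds, list(n_levels = as.integer(n_levels),
                           duration_h = duration_h)),
            class = "dcf_design")
}

design_factors <- function(design)
  c("q_set_lph", "c_feed_gpl", "rcake_ss_ref_per_m")

#' Full factorial design
#'
#' Cartesian product of `n_levels` evenly spaced levels (endpoints included)
#' per factor, in deterministic lexicographic order: the first declared
#' factor varies slowest.
#'
#' @param design a [dcf_design_space()] object.
#' @return data.frame with one row per design point and one column per factor.
#' @export
full_factorial <- function(design) {
  f <- design_factors(design)
  levels <- lapply(f, function(nm)
    seq(design[[nm]][1], design[[nm]][2], length.out = design$n_levels))
  names(levels) <- f
  g <- expand.grid(rev(levels), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(f)), drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Min-max factor scaling to the unit interval
#'
#' `x' = (x - low) / (high - low)` per factor; `unscale_factors()` is the
#' inverse. Points outside the design bounds are allowed but flagged with a
#' warning (the metamodel has no extrapolation capability).
#'
#' @param points data.frame (or named list/vector) with the design factors in
#'   raw units.
#' @param design a [dcf_design_space()] object.
#' @param warn warn when a point lies outside the design bounds.
#' @return data.frame of scaled coordinates in the same factor order.
#' @export
scale_factors <- function(points, design, warn = TRUE) {
  f <- design_factors(design)
  points <- as.data.frame(as.list(points))[f]
  out <- points
  outside <- FALSE
  for (nm in f) {
    b <- design[[nm]]
    if (b[1] == b[2]) stop("scale_factors: degenerate bounds for ", nm,
                           call. = FALSE)
    out[[nm]] <- (points[[nm]] - b[1]) / (b[2] - b[1])
    outside <- outside || any(out[[nm]] < -1e-9 | out[[nm]] > 1 + 1e-9)
  }
  if (warn && outside)
    warning("scale_factors: point outside the design space (metamodel is ",
            "not trained there)", call. = FALSE)
  out
}

#' @rdname scale_factors
#' @export
unscale_factors <- function(points, design) {
  f <- design_factors(design)
  points <- as.data.frame(as.list(points))[f]
  for (nm in f) {
    b <- design[[nm]]
    points[[nm]] <- b[1] + points[[nm]] * (b[2] - b[1])
  }
  points
}

# Polynomial rolling hash over the serialised design + parameters: content
# hash for the in-session DoE cache.
content_hash <- function(...) {
  bytes <- as.integer(serialize(list(...), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b + 1) %% 2147483629
  sprintf("%x-%d", h, length(bytes))
}

.doe_cache <- new.env(parent = emptyenv())

#' Run the in-silico design of experiments
#'
#' One process simulation per design point ([simulate_run()] with the
#' point's initial setpoint, feed concentration and reference steady-state
#' cake resistance; constant setpoint, no schedule), each over the design's
#' run duration, returning the productivity response. Results are cached
#' in-session under a content hash of design + parameters, so refits are
#' bit-identical and free.
#'
#' @param design a [dcf_design_space()] object.
#' @param params a [dcf_model_parameters()] object.
#' @param config a [dcf_plant_config()] object.
#' @param cache use the in-session result cache.
#' @param progress print one line per completed run.
#' @return data.frame: factor columns plus `productivity_lph`.
#' @export
run_doe <- function(design, params, config = dcf_plant_config(),
                    cache = TRUE, progress = FALSE) {
  key <- content_hash(unclass(design), unclass(params), unclass(config))
  if (cache && !is.null(.doe_cache[[key]])) return(.doe_cache[[key]])
  pts <- full_factorial(design)
  prod <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    scen <- dcf_scenario(pts$q_set_lph[i], pts$c_feed_gpl[i],
                         design$duration_h)
    run <- simulate_run(scen, params, config,
                        rcake_ss_ref_per_m = pts$rcake_ss_ref_per_m[i],
                        keep_log = FALSE)
    prod[i] <- productivity(run)
    if (progress)
      message(sprintf("doe %3d/%d: Qset=%6.0f c=%5.1f R=%.2e -> P=%6.1f",
                      i, nrow(pts), pts$q_set_lph[i], pts$c_feed_gpl[i],
                      pts$rcake_ss_ref_per_m[i], prod[i]))
  }
  res <- cbind(pts, productivity_lph = prod)
  if (cache) .doe_cache[[key]] <- res
  res
}

# 10-term quadratic basis in the scaled coordinates, coefficient order
# w0 (bias), w1 c, w2 q, w3 r, w4 c^2, w5 c*q, w6 c*r, w7 q^2, w8 q*r, w9 r^2
# (c = feed concentration, q = permeate setpoint, r = cake resistance).
surface_basis <- function(xc, xq, xr) {
  cbind(w0 = 1, w1 = xc, w2 = xq, w3 = xr,
        w4 = xc^2, w5 = xc * xq, w6 = xc * xr,
        w7 = xq^2, w8 = xq * xr, w9 = xr^2)
}

#' Fit the quadratic response surface
#'
#' Ordinary least squares of the productivity response on the full quadratic
#' basis (bias, 3 linear, 3 square, 3 interaction terms) in the unit-scaled
#' factor space. With 125 full-factorial points and 10 coefficients no
#' regularisation is needed; the fit interpolates exactly whenever the
#' generating response is itself quadratic.
#'
#' @param doe a DoE table from [run_doe()] (factor columns +
#'   `productivity_lph`), no missing responses.
#' @param design the [dcf_design_space()] the table was generated from.
#' @return an object of class `dcf_surface`: coefficients `w0..w9`, the
#'   design (scaling metadata), per-point residuals and R^2.
#' @export
fit_response_surface <- function(doe, design) {
  if (any(!is.finite(doe$productivity_lph)))
    stop("fit_response_surface: missing/non-finite responses", call. = FALSE)
  if (nrow(doe) < 10)
    stop("fit_response_surface: need at least 10 design points", call. = FALSE)
  sc <- scale_factors(doe[design_factors(design)], design, warn = FALSE)
  B <- surface_basis(sc$c_feed_gpl, sc$q_set_lph, sc$rcake_ss_ref_per_m)
  if (qr(B)$rank < ncol(B))
    stop("fit_response_surface: rank-deficient design", call. = FALSE)
  fit <- lm.fit(B, doe$productivity_lph)
  w <- fit$coefficients
  res <- fit$residuals
  ss_tot <- sum((doe$productivity_lph - mean(doe$productivity_lph))^2)
  structure(list(
    coefficients = w,
    design = design,
    residuals_lph = res,
    r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
    doe = doe
  ), class = "dcf_surface")
}

#' Predict productivity from the response surface
#'
#' Evaluates the fitted 10-term polynomial at raw-unit inputs (scaled
#' internally with the surface's stored design bounds). Warns outside the
#' trained design space.
#'
#' @param surface a `dcf_surface` from [fit_response_surface()].
#' @param c_feed_gpl feed concentration, g/L.
#' @param q_set_lph initial permeate setpoint, L/h.
#' @param rcake_ss_ref_per_m reference steady-state cake resistance, m^-1.
#' @return predicted productivity, L/h (vectorised over the inputs).
#' @export
predict_productivity <- function(surface, c_feed_gpl, q_set_lph,
                                 rcake_ss_ref_per_m) {
  sc <- scale_factors(data.frame(q_set_lph = q_set_lph,
                                 c_feed_gpl = c_feed_gpl,
                                 rcake_ss_ref_per_m = rcake_ss_ref_per_m),
                      surface$design)
  drop(surface_basis(sc$c_feed_gpl, sc$q_set_lph, sc$rcake_ss_ref_per_m) %*%
         surface$coefficients)
}

#' Analytic optimal permeate setpoint
#'
#' Stationary point of the response surface along the setpoint axis,
#' `x_q* = -(w2 + w5 c' + w8 r') / (2 w7)` in scaled coordinates, accepted as
#' an interior maximum only when the second-derivative condition `2 w7 < 0`
#' holds and the point lies inside the unit interval. Otherwise the design
#' bound with the higher predicted productivity is returned and flagged as a
#' boundary optimum (the surface is not trusted outside its design space).
#'
#' @param surface a `dcf_surface`.
#' @param c_feed_gpl current feed concentration, g/L.
#' @param rcake_ss_ref_per_m current reference steady-state cake resistance,
#'   m^-1.
#' @return list with `q_set_lph` (the recommended setpoint),
#'   `predicted_productivity_lph`, and `boundary` (TRUE if the maximum was
#'   clipped to a design bound).
#' @export
optimal_setpoint <- function(surface, c_feed_gpl, rcake_ss_ref_per_m) {
  design <- surface$design
  sc <- scale_factors(data.frame(q_set_lph = design$q_set_lph[1],
                                 c_feed_gpl = c_feed_gpl,
                                 rcake_ss_ref_per_m = rcake_ss_ref_per_m),
                      design)
  w <- surface$coefficients
  xc <- sc$c_feed_gpl
  xr <- sc$rcake_ss_ref_per_m
  pred_at <- function(xq)
    drop(surface_basis(xc, xq, xr) %*% w)

  interior <- FALSE
  xq_star <- NA_real_
  if (2 * w[["w7"]] < 0) {
    xq_star <- -(w[["w2"]] + w[["w5"]] * xc + w[["w8"]] * xr) /
      (2 * w[["w7"]])
    interior <- xq_star >= 0 && xq_star <= 1
  }
  if (!interior) {
    xq_star <- if (pred_at(1) >= pred_at(0)) 1 else 0
  }
  q_raw <- design$q_set_lph[1] +
    xq_star * (design$q_set_lph[2] - design$q_set_lph[1])
  list(q_set_lph = q_raw,
       predicted_productivity_lph = pred_at(xq_star),
       boundary = !interior)
}

#' @export
print.dcf_surface <- function(x, ...) {
  cat("DCF response surface (productivity, L/h, on unit-scaled factors)\n")
  print(round(x$coefficients, 2))
  cat(sprintf("R^2 = %.4f; |residual| p95 = %.1f L/h (n = %d)\n",
              x$r_squared, stats::quantile(abs(x$residuals_lph), 0.95),
              length(x$residuals_lph)))
  invisible(x)
}

#' Write / read a fitted surface as JSON
#'
#' Stores coefficients, the design-space scaling metadata and fit
#' diagnostics.
#'
#' @param surface a `dcf_surface`.
#' @param path file path.
#' @return `read_surface()` returns the `dcf_surface` (without the training
#'   table).
#' @export
write_surface <- function(surface, path) {
  jsonlite::write_json(list(
    coefficients = as.list(surface$coefficients),
    design = unclass(surface$design),
    residuals_lph = surface$residuals_lph,
    r_squared = surface$r_squared,
    tool_version = as.character(utils::packageVersion("dcftwin"))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- dcf_design_space(
    q_set_lph = as.numeric(x$design$q_set_lph),
    c_feed_gpl = as.numeric(x$design$c_feed_gpl),
    rcake_ss_ref_per_m = as.numeric(x$design$rcake_ss_ref_per_m),
    n_levels = x$design$n_levels,
    duration_h = x$design$duration_h)
  structure(list(coefficients = unlist(x$coefficients),
                 design = design,
                 residuals_lph = as.numeric(x$residuals_lph),
                 r_squared = x$r_squared,
                 doe = NULL),
            class = "dcf_surface")
}
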