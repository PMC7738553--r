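# von Mises sampler, Best & Fisher (1979) rejection method.
# mu in radians; kappa = 0 falls back to uniform, kappa = Inf is degenerate.
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Generator settings for synthetic iridophore tracks
#'
#' Parameters of the synthetic time-lapse generator. Positions are in um on
#' an anterior-posterior (x, increasing posterior) / dorso-ventral
#' (y, increasing dorsal) plane; frames are `dt_min` minutes apart over
#' `duration_hr` hours (defaults: 5 min frames, 15 h movies). Dense
#' (interstripe) cells jitter with near-zero drift and divide along the AP
#' axis (von Mises concentration `kappa_dense` in doubled-angle space);
#' loose (stripe) cells execute random walks with a configurable
#' dorso-ventral drift per frame (negative = ventral, away from the primary
#' interstripe) and divide with uniformly distributed plane orientations.
#' Division events are Poisson with class-specific rates per cell-hour.
#'
#' @param duration_hr movie length, hours.
#' @param dt_min frame interval, minutes.
#' @param jitter_dense_um,jitter_loose_um per-frame isotropic positional
#'   jitter SD, um.
#' @param drift_loose_um dorso-ventral drift of loose cells per frame, um
#'   (negative = ventral).
#' @param kappa_dense von Mises concentration of dense division angles in
#'   doubled-angle space (`Inf` = all divisions exactly AP).
#' @param rate_dense,rate_loose division rates, events per cell-hour.
#' @return A `"track_params"` list.
#' @export
track_params <- function(duration_hr = 15, dt_min = 5,
                         jitter_dense_um = 0.3, jitter_loose_um = 2,
                         drift_loose_um = -0.5, kappa_dense = 4,
                         rate_dense = 0.005, rate_loose = 0.01) {
  if (duration_hr <= 0 || dt_min <= 0) stop("durations must be > 0")
  if (jitter_dense_um < 0 || jitter_loose_um < 0) stop("jitter must be >= 0")
  if (kappa_dense < 0) stop("'kappa_dense' must be >= 0")
  if (rate_dense < 0 || rate_loose < 0) stop("rates must be >= 0")
  structure(as.list(environment()), class = "track_params")
}

#' Generate a synthetic time-lapse track dataset
#'
#' Seeded synthetic stand-in for membrane-label time-lapse recordings of
#' iridophores: per-cell position tracks and division events with
#' division-plane angles, for dense and loose cell classes (see
#' [track_params()] for the behavioural model).
#'
#' @param n_dense,n_loose number of cells per class (>= 0).
#' @param params a [track_params()] object.
#' @param seed optional integer seed.
#' @return A `"track_dataset"` list with data frames `tracks`
#'   (`cell_id`, `class`, `t_hr`, `x_um`, `y_um`) and `divisions`
#'   (`cell_id`, `t_hr`, `angle_deg` with axial angles in `[0, 180)`).
#' @examples
#' td <- generate_tracks(5, 5, seed = 1)
#' head(td$tracks)
#' @export
generate_tracks <- function(n_dense, n_loose, params = track_params(),
                            seed = NULL) {
  if (!inherits(params, "track_params")) stop("'params' must be track_params")
  if (n_dense < 0 || n_loose < 0) stop("cell counts must be >= 0")
  n_dense <- as.integer(n_dense); n_loose <- as.integer(n_loose)
  t_hr <- seq(0, params$duration_hr, by = params$dt_min / 60)
  nf <- length(t_hr)
  with_seed_(seed, {
    make_cells <- function(n, class) {
      if (n == 0L) return(list(tracks = NULL, divisions = NULL))
      jitter <- if (class == "dense") params$jitter_dense_um else params$jitter_loose_um
      drift <- if (class == "dense") 0 else params$drift_loose_um
      rate <- if (class == "dense") params$rate_dense else params$rate_loose
      tr <- vector("list", n); dv <- vector("list", n)
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", class, i)
        x0 <- stats::runif(1, 0, 500); y0 <- stats::runif(1, 0, 500)
        dx <- if (jitter > 0) stats::rnorm(nf - 1L, 0, jitter) else numeric(nf - 1L)
        dy <- if (jitter > 0) stats::rnorm(nf - 1L, drift, jitter) else rep(drift, nf - 1L)
        tr[[i]] <- data.frame(cell_id = id, class = class, t_hr = t_hr,
                              x_um = x0 + c(0, cumsum(dx)),
                              y_um = y0 + c(0, cumsum(dy)))
        ndiv <- stats::rpois(1, rate * params$duration_hr)
        if (ndiv > 0L) {
          ang <- if (class == "dense") {
            (rvonmises(ndiv, 0, params$kappa_dense) / 2 * 180 / pi) %% 180
          } else {
            stats::runif(ndiv, 0, 180)
          }
          dv[[i]] <- data.frame(cell_id = id,
                                t_hr = sort(stats::runif(ndiv, 0, params$duration_hr)),
                                angle_deg = ang)
        }
      }
      list(tracks = do.call(rbind, tr), divisions = do.call(rbind, dv))
    }
    d <- make_cells(n_dense, "dense")
    l <- make_cells(n_loose, "loose")
    empty_tracks <- data.frame(cell_id = character(0), class = character(0),
                               t_hr = numeric(0), x_um = numeric(0), y_um = numeric(0))
    empty_div <- data.frame(cell_id = character(0), t_hr = numeric(0),
                            angle_deg = numeric(0))
    tracks <- rbind(d$tracks, l$tracks)
    divisions <- rbind(d$divisions, l$divisions)
    structure(list(tracks = if (is.null(tracks)) empty_tracks else tracks,
                   divisions = if (is.null(divisions)) empty_div else divisions,
                   params = params, seed = seed),
              class = "track_dataset")
  })
}

#' @export
print.track_dataset <- function(x, ...) {
  tab <- table(x$tracks$class[!duplicated(x$tracks$cell_id)])
  cat(sprintf("Track dataset: %d cells (%s), %d divisions\n",
              sum(tab), paste(names(tab), tab, sep = "=", collapse = ", "),
              nrow(x$divisions)))
  invisible(x)
}

# Rayleigh uniformity test on circular angles (radians); returns the
# standard small-sample corrected p-value (Zar 1999).
rayleigh_test <- function(theta) {
  n <- length(theta)
  Rsum <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2)
  rbar <- Rsum / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rsum^2)) - (1 + 2 * n))
  list(rbar = rbar, p = min(max(p, 0), 1))
}

#' Axial statistics of division-plane angles
#'
#' Division planes are orientations, defined modulo 180 degrees; statistics
#' are computed in doubled-angle space (the standard axial-data device):
#' the mean direction and resultant length of the doubled angles, halved
#' back to an axial mean in `[0, 180)`, and a Rayleigh test of uniformity.
#' A resultant length near 1 means strongly aligned division planes; 0
#' means no preferred axis (the mean axis is then `NA`).
#'
#' @param angles axial angles in degrees (any values; reduced modulo 180).
#' @return An `"axial_stats"` list: `n`, `mean_axis` (degrees in
#'   `[0, 180)`), `resultant_length` in `[0, 1]`, `p_uniform`.
#' @examples
#' division_angle_stats(c(0, 10, 170))  # AP-concentrated
#' @export
division_angle_stats <- function(angles) {
  if (length(angles) == 0L) stop("need at least one angle")
  if (any(!is.finite(angles))) stop("angles must be finite")
  doubled <- 2 * (angles %% 180) * pi / 180
  C <- sum(cos(doubled)); S <- sum(sin(doubled))
  n <- length(angles)
  rbar <- sqrt(C^2 + S^2) / n
  mean_axis <- if (rbar < 1e-12) NA_real_ else (atan2(S, C) * 180 / pi / 2) %% 180
  rl <- rayleigh_test(doubled)
  structure(list(n = n, mean_axis = mean_axis, resultant_length = rbar,
                 p_uniform = rl$p),
            class = "axial_stats")
}

#' @export
print.axial_stats <- function(x, ...) {
  cat(sprintf("Axial stats (n = %d): mean axis %s deg, R = %.3f, Rayleigh p = %.4g\n",
              x$n,
              if (is.na(x$mean_axis)) "NA" else sprintf("%.1f", x$mean_axis),
              x$resultant_length, x$p_uniform))
  invisible(x)
}

#' Migration bias of one cell class
#'
#' Net start-to-end displacement of every cell of the class that moved at
#' least `min_displacement` um (default 20 um, one nominal cell diameter).
#' Reports the mean dorso-ventral (y) displacement component with a
#' percentile bootstrap confidence interval and the fraction of qualifying
#' cells that moved ventrally, i.e. away from the primary interstripe
#' (which lies dorsal to the stripe in the modelled field of view).
#'
#' @param dataset a `"track_dataset"` (or compatible list with `$tracks`).
#' @param cls cell class to analyze.
#' @param min_displacement qualification threshold on net displacement, um.
#' @param n_boot bootstrap replicates for the CI.
#' @param conf confidence level.
#' @param seed optional integer seed for the bootstrap.
#' @return A `"migration_report"` list: `n_cells`, `n_qualifying`,
#'   `mean_dv_um`, `ci_dv_um`, `fraction_away`, `displacements` (data
#'   frame), and `empty` flag when no cell qualifies.
#' @export
migration_bias <- function(dataset, cls = "loose", min_displacement = 20,
                           n_boot = 1000, conf = 0.95, seed = NULL) {
  tracks <- dataset$tracks
  if (is.null(tracks) || nrow(tracks) == 0L) stop("track dataset is empty")
  tracks <- tracks[tracks$class == cls, , drop = FALSE]
  ids <- unique(tracks$cell_id)
  if (nrow(tracks) > 0L) {
    o <- order(tracks$cell_id, tracks$t_hr)
    x <- split(tracks$x_um[o], tracks$cell_id[o])
    y <- split(tracks$y_um[o], tracks$cell_id[o])
    net <- function(v) vapply(v, function(p) p[length(p)] - p[1L], numeric(1))
    disp <- data.frame(cell_id = names(x), dx_um = net(x), dy_um = net(y),
                       row.names = NULL)
  } else {
    disp <- data.frame(cell_id = character(0),
                       dx_um = numeric(0), dy_um = numeric(0))
  }
  qual <- disp[sqrt(disp$dx_um^2 + disp$dy_um^2) >= min_displacement, , drop = FALSE]
  if (nrow(qual) == 0L) {
    return(structure(list(class = cls, n_cells = length(ids), n_qualifying = 0L,
                          mean_dv_um = NA_real_, ci_dv_um = c(NA_real_, NA_real_),
                          fraction_away = NA_real_, displacements = qual,
                          empty = TRUE),
                     class = "migration_report"))
  }
  dv <- qual$dy_um
  ci <- with_seed_(seed, {
    boots <- vapply(seq_len(n_boot),
                    function(i) mean(sample(dv, replace = TRUE)), numeric(1))
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  structure(list(class = cls, n_cells = length(ids),
                 n_qualifying = nrow(qual),
                 mean_dv_um = mean(dv), ci_dv_um = ci,
                 fraction_away = mean(dv < 0),
                 displacements = qual, empty = FALSE),
            class = "migration_report")
}

#' @export
print.migration_report <- function(x, ...) {
  cat(sprintf("Migration bias (%s cells): %d/%d moved >= threshold\n",
              x$class, x$n_qualifying, x$n_cells))
  if (!x$empty)
    cat(sprintf("  mean DV displacement %.2f um (CI %.2f to %.2f); %.0f%% moved ventrally\n",
                x$mean_dv_um, x$ci_dv_um[1], x$ci_dv_um[2],
                100 * x$fraction_away))
  invisible(x)
}

#' Per-class proliferation rates
#'
#' Divisions per cell-hour for each cell class, with exact Poisson
#' confidence intervals ([stats::poisson.test()]) and, when both classes are
#' present, an exact rate-ratio test of loose versus dense proliferation.
#' Observation time per cell is the span of its track timestamps, so the
#' rates are invariant to splitting a track into contiguous pieces.
#'
#' @param dataset a `"track_dataset"`.
#' @param conf confidence level.
#' @return A `"proliferation_report"`: per-class `divisions`,
#'   `cell_hours`, `rate`, `ci`, plus `ratio` (loose/dense estimate, CI and
#'   p-value) when both classes are observed.
#' @export
proliferation_rates <- function(dataset, conf = 0.95) {
  tracks <- dataset$tracks
  divisions <- dataset$divisions
  if (is.null(tracks) || nrow(tracks) == 0L) stop("track dataset is empty")
  per_cell <- stats::aggregate(t_hr ~ cell_id + class, data = tracks,
                               FUN = function(t) max(t) - min(t))
  if (any(per_cell$t_hr <= 0) || sum(per_cell$t_hr) <= 0)
    stop("zero observation time in track dataset")
  classes <- sort(unique(per_cell$class))
  out <- list()
  for (cl in classes) {
    hours <- sum(per_cell$t_hr[per_cell$class == cl])
    ids <- per_cell$cell_id[per_cell$class == cl]
    x <- sum(divisions$cell_id %in% ids)
    pt <- stats::poisson.test(x, hours, conf.level = conf)
    out[[cl]] <- list(divisions = x, cell_hours = hours,
                      rate = x / hours, ci = unname(pt$conf.int))
  }
  if (all(c("dense", "loose") %in% classes)) {
    rt <- stats::poisson.test(c(out$loose$divisions, out$dense$divisions),
                              c(out$loose$cell_hours, out$dense$cell_hours),
                              conf.level = conf)
    out$ratio <- list(estimate = unname(rt$estimate), ci = unname(rt$conf.int),
                      p_value = rt$p.value, comparison = "loose vs dense")
  }
  structure(out, class = "proliferation_report")
}

#' @export
print.proliferation_report <- function(x, ...) {
  cat("Proliferation rates (divisions per cell-hour)\n")
  for (cl in setdiff(names(x), "ratio")) {
    r <- x[[cl]]
    cat(sprintf("  %-6s %d divisions / %.0f cell-hours = %.4f (CI %.4f-%.4f)\n",
                cl, r$divisions, r$cell_hours, r$rate, r$ci[1], r$ci[2]))
  }
  if (!is.null(x$ratio))
    cat(sprintf("  rate ratio %s: %.2f (CI %.2f-%.2f), p = %.3g\n",
                x$ratio$comparison, x$ratio$estimate, x$ratio$ci[1],
                x$ratio$ci[2], x$ratio$p_value))
  invisible(x)
}
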