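#' @keywords internal
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# Truncated-normal draws by rejection; floor is a hard physical lower bound.
rnorm_floor <- function(n, mean, sd, floor) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < floor) stop("degenerate distribution entirely below floor")
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < floor)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < floor]
  }
  out
}

#' Sample layer thicknesses for one material of a crystallotype
#'
#' Draws thicknesses (nm) from the preset's normal distribution for the given
#' material, rejection-resampled until every draw is at least `floor_nm`
#' (default 5 nm; thinner layers are taken as nonphysical).
#'
#' @param preset a [crystallotype_preset()].
#' @param material `"crystal"` or `"cytoplasm"`.
#' @param n number of draws.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param floor_nm hard lower bound, nm.
#' @return Numeric vector of `n` thicknesses in nm.
#' @export
sample_layer_thicknesses <- function(preset, material = c("crystal", "cytoplasm"),
                                     n, seed = NULL, floor_nm = 5) {
  if (!is_preset(preset)) stop("'preset' must be a crystallotype_preset")
  material <- match.arg(material)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  m <- if (material == "crystal") preset$crystal_thickness_mean else preset$cytoplasm_mean
  s <- if (material == "crystal") preset$crystal_thickness_sd else preset$cytoplasm_sd
  with_seed_(seed, rnorm_floor(as.integer(n), m, s, floor_nm))
}

#' Sample a random layer stack from a crystallotype preset
#'
#' Draws the number of crystal layers uniformly from the preset's range, then
#' draws each layer thickness from the preset's normal distribution
#' (rejection-resampled below `floor_nm`). The stack alternates
#' crystal/cytoplasm/crystal/... and begins and ends with a crystal layer,
#' so a stack with L crystal layers carries L-1 cytoplasm spacings.
#'
#' @inheritParams sample_layer_thicknesses
#' @return A `"layer_stack"`: a data frame with columns `material`,
#'   `refractive_index` and `thickness_nm`, one row per layer, top first.
#' @examples
#' stk <- sample_stack(default_presets("ordered"), seed = 1)
#' table(stk$material)
#' @export
sample_stack <- function(preset, seed = NULL, floor_nm = 5) {
  if (!is_preset(preset)) stop("'preset' must be a crystallotype_preset")
  with_seed_(seed, {
    L <- preset$layer_count_min +
      sample.int(preset$layer_count_max - preset$layer_count_min + 1L, 1L) - 1L
    d_cry <- rnorm_floor(L, preset$crystal_thickness_mean,
                         preset$crystal_thickness_sd, floor_nm)
    d_cyt <- rnorm_floor(L - 1L, preset$cytoplasm_mean,
                         preset$cytoplasm_sd, floor_nm)
    layer_stack(d_cry, d_cyt, preset$n_crystal, preset$n_cytoplasm)
  })
}

#' Build a layer stack from explicit thicknesses
#'
#' @param d_crystal thicknesses (nm) of the crystal layers, top first.
#' @param d_cytoplasm thicknesses (nm) of the cytoplasm spacings between
#'   them; must be one shorter than `d_crystal` (crystal-terminated stack),
#'   or length zero for a single-layer stack.
#' @param n_crystal,n_cytoplasm refractive indices.
#' @return A `"layer_stack"` data frame (see [sample_stack()]).
#' @export
layer_stack <- function(d_crystal, d_cytoplasm = numeric(0),
                        n_crystal = 1.83, n_cytoplasm = 1.33) {
  L <- length(d_crystal)
  if (L == 0L) {
    out <- data.frame(material = character(0), refractive_index = numeric(0),
                      thickness_nm = numeric(0))
    class(out) <- c("layer_stack", "data.frame")
    return(out)
  }
  if (length(d_cytoplasm) != L - 1L)
    stop("need length(d_cytoplasm) == length(d_crystal) - 1")
  if (any(d_crystal <= 0) || any(d_cytoplasm <= 0))
    stop("all thicknesses must be > 0")
  material <- rep("crystal", 2L * L - 1L)
  thick <- numeric(2L * L - 1L)
  thick[seq(1L, 2L * L - 1L, by = 2L)] <- d_crystal
  if (L > 1L) {
    material[seq(2L, 2L * L - 2L, by = 2L)] <- "cytoplasm"
    thick[seq(2L, 2L * L - 2L, by = 2L)] <- d_cytoplasm
  }
  out <- data.frame(
    material = material,
    refractive_index = ifelse(material == "crystal", n_crystal, n_cytoplasm),
    thickness_nm = thick
  )
  class(out) <- c("layer_stack", "data.frame")
  out
}

#' Deterministic stack at the preset means
#'
#' Zero-variance counterpart of [sample_stack()]: every crystal layer at the
#' preset's mean thickness, every spacing at the mean spacing, and the layer
#' count at the midpoint of the preset's range (rounded down).
#'
#' @inheritParams sample_stack
#' @param n_layers optional explicit crystal-layer count.
#' @return A `"layer_stack"` data frame.
#' @export
mean_stack <- function(preset, n_layers = NULL) {
  if (!is_preset(preset)) stop("'preset' must be a crystallotype_preset")
  L <- if (is.null(n_layers))
    (preset$layer_count_min + preset$layer_count_max) %/% 2L
  else as.integer(n_layers)
  layer_stack(rep(preset$crystal_thickness_mean, L),
              rep(preset$cytoplasm_mean, max(L - 1L, 0L)),
              preset$n_crystal, preset$n_cytoplasm)
}

#' @export
print.layer_stack <- function(x, ...) {
  k <- sum(x$material == "crystal")
  cat(sprintf("Layer stack: %d layers (%d crystal, %d cytoplasm)\n",
              nrow(x), k, nrow(x) - k))
  if (nrow(x) > 0L)
    cat(sprintf("  optical thickness sum(n*d): %.1f nm\n",
                sum(x$refractive_index * x$thickness_nm)))
  NextMethod()
}

#' Synthetic crystal morphometry sample
#'
#' Emulates TEM measurements of isolated guanine crystals: lengths are drawn
#' from a normal distribution truncated above 0, aspect ratios
#' (length/width) from a normal truncated at >= 1, and widths are derived as
#' length / aspect ratio so the printed ratio definition holds exactly.
#'
#' @param mean_len,sd_len length distribution, um.
#' @param mean_ar,sd_ar aspect-ratio distribution (dimensionless, >= 1).
#' @param n sample size (>= 1).
#' @param crystallotype label attached to the sample, e.g. `"stripe"`.
#' @param seed optional integer seed.
#' @return A `"morphometry_sample"` data frame with columns `length_um`,
#'   `width_um`, `aspect_ratio`, `crystallotype`.
#' @examples
#' m <- sample_morphometry(3.9, 0.4, 1.9, 0.2, n = 60, seed = 1)
#' colMeans(m[c("length_um", "aspect_ratio")])
#' @export
sample_morphometry <- function(mean_len, sd_len, mean_ar, sd_ar, n,
                               crystallotype = "unlabelled", seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a count >= 1")
  if (mean_len <= 0 || mean_ar < 1) stop("mean length must be > 0 and mean aspect ratio >= 1")
  if (sd_len < 0 || sd_ar < 0) stop("SDs must be >= 0")
  n <- as.integer(n)
  with_seed_(seed, {
    len <- rnorm_floor(n, mean_len, sd_len, .Machine$double.eps)
    ar <- rnorm_floor(n, mean_ar, sd_ar, 1)
    out <- data.frame(length_um = len, width_um = len / ar,
                      aspect_ratio = ar,
                      crystallotype = rep(crystallotype, n))
    class(out) <- c("morphometry_sample", "data.frame")
    out
  })
}

#' Built-in morphometry parameter sets
#'
#' TEM-derived crystal length and aspect-ratio parameters for crystals
#' isolated from stripe iridophores (3.9 +/- 0.4 um, AR 1.9 +/- 0.2, n = 60)
#' and interstripe iridophores (5.3 +/- 0.9 um, AR 2.5 +/- 0.3, n = 57).
#'
#' @return Named list of parameter lists
#'   (`mean_len`, `sd_len`, `mean_ar`, `sd_ar`, `n`).
#' @export
morphometry_presets <- function() {
  list(
    stripe = list(mean_len = 3.9, sd_len = 0.4, mean_ar = 1.9, sd_ar = 0.2, n = 60L),
    interstripe = list(mean_len = 5.3, sd_len = 0.9, mean_ar = 2.5, sd_ar = 0.3, n = 57L)
  )
}

# Exact two-sided permutation test on the rank sum of group a.
# Feasible only for small samples; p = share of assignments whose rank sum
# deviates from its permutation mean at least as much as observed.
rank_sum_perm_test <- function(a, b) {
  v <- c(a, b)
  r <- rank(v)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  idx <- utils::combn(length(v), na)
  sums <- colSums(matrix(r[idx], nrow = na))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

#' Compare two morphometry samples
#'
#' Reports per-group mean +/- SEM for length and aspect ratio and a
#' two-sided rank-sum (Mann-Whitney) p-value on the aspect ratios. For small
#' samples (at most `exact_max` combined observations) the exact permutation
#' distribution of the rank sum is enumerated; larger samples use
#' [stats::wilcox.test()] with the normal approximation.
#'
#' @param a,b `morphometry_sample` data frames (non-empty).
#' @param exact_max largest combined sample size for which the permutation
#'   distribution is enumerated exhaustively.
#' @return A `"morphometry_comparison"` list: `groups` (means/SEMs/n) and
#'   `p_value` (aspect ratios).
#' @export
summarize_morphometry <- function(a, b, exact_max = 12L) {
  for (s in list(a, b)) {
    if (!is.data.frame(s) || nrow(s) == 0L)
      stop("both samples must be non-empty morphometry data frames")
    if (!all(c("length_um", "aspect_ratio") %in% names(s)))
      stop("samples need 'length_um' and 'aspect_ratio' columns")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  grp <- function(s) list(
    n = nrow(s),
    mean_length_um = mean(s$length_um), sem_length_um = sem(s$length_um),
    mean_aspect_ratio = mean(s$aspect_ratio), sem_aspect_ratio = sem(s$aspect_ratio),
    crystallotype = s$crystallotype[1L]
  )
  x <- a$aspect_ratio; y <- b$aspect_ratio
  p <- if (length(x) + length(y) <= exact_max) {
    rank_sum_perm_test(x, y)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  structure(list(groups = list(a = grp(a), b = grp(b)), p_value = p,
                 statistic = "two-sided rank sum on aspect ratios"),
            class = "morphometry_comparison")
}

#' @export
print.morphometry_comparison <- function(x, ...) {
  cat("Morphometry comparison (aspect ratio rank-sum test)\n")
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %s (%s, n=%d): length %.2f +/- %.2f um, AR %.2f +/- %.2f\n",
                nm, g$crystallotype, g$n, g$mean_length_um, g$sem_length_um,
                g$mean_aspect_ratio, g$sem_aspect_ratio))
  }
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}
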