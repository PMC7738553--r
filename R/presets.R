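#' Crystallotype presets
#'
#' A crystallotype preset bundles the morphometric parameters of one
#' iridophore subtype: the normal distributions of guanine-crystal thickness
#' and cytoplasm spacing (nm), the range of crystal layer counts per stack,
#' and the refractive indices of the two materials. Two presets ship with
#' the package: `"ordered"` (stripe iridophores: thin crystals in 20--30
#' parallel layers, narrow spacing distribution) and `"disordered"`
#' (interstripe iridophores: similar crystal thickness but widely varying
#' spacing, 30--40 crystals).
#'
#' @param name preset label, e.g. `"ordered"` or `"disordered"`.
#' @param crystal_thickness_mean,crystal_thickness_sd mean and SD of guanine
#'   crystal thickness, nm.
#' @param cytoplasm_mean,cytoplasm_sd mean and SD of the cytoplasm spacing
#'   between crystals, nm.
#' @param layer_count_min,layer_count_max inclusive range of the number of
#'   crystal layers per stack.
#' @param n_crystal refractive index of crystalline guanine (default 1.83).
#' @param n_cytoplasm refractive index of cytoplasm (default 1.33, aqueous).
#'
#' @return An object of class `"crystallotype_preset"` (a named list).
#' @examples
#' crystallotype_preset("ordered", 27, 7, 131, 24, 20, 30)
#' @export
crystallotype_preset <- function(name,
                                 crystal_thickness_mean, crystal_thickness_sd,
                                 cytoplasm_mean, cytoplasm_sd,
                                 layer_count_min, layer_count_max,
                                 n_crystal = 1.83, n_cytoplasm = 1.33) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (v in list(crystal_thickness_mean, crystal_thickness_sd,
                 cytoplasm_mean, cytoplasm_sd,
                 layer_count_min, layer_count_max, n_crystal, n_cytoplasm)) {
    if (!num1(v)) stop("preset parameters must be finite numeric scalars")
  }
  if (crystal_thickness_mean <= 0 || cytoplasm_mean <= 0)
    stop("thickness and spacing means must be > 0")
  if (crystal_thickness_sd < 0 || cytoplasm_sd < 0)
    stop("thickness and spacing SDs must be >= 0")
  if (layer_count_min < 1 || layer_count_max < layer_count_min)
    stop("need 1 <= layer_count_min <= layer_count_max")
  if (n_cytoplasm < 1) stop("n_cytoplasm must be >= 1")
  if (n_crystal <= n_cytoplasm)
    stop("n_crystal must exceed n_cytoplasm (high-index crystal layers)")
  structure(list(
    name = name,
    crystal_thickness_mean = crystal_thickness_mean,
    crystal_thickness_sd = crystal_thickness_sd,
    cytoplasm_mean = cytoplasm_mean,
    cytoplasm_sd = cytoplasm_sd,
    layer_count_min = as.integer(layer_count_min),
    layer_count_max = as.integer(layer_count_max),
    n_crystal = n_crystal,
    n_cytoplasm = n_cytoplasm
  ), class = "crystallotype_preset")
}

#' Built-in crystallotype presets
#'
#' Returns the cryo-SEM-derived default parameter sets for the two
#' iridophore crystallotypes: ordered (stripe) stacks of 20--30 crystal
#' layers, 27 +/- 7 nm thick, spaced by 131 +/- 24 nm of cytoplasm;
#' disordered (interstripe) stacks of 30--40 crystals, 25 +/- 8 nm thick,
#' spaced by 186 +/- 81 nm. Guanine index 1.83, cytoplasm 1.33.
#'
#' @param which `"ordered"`, `"disordered"`, or `"all"` (default) for a
#'   named list of both.
#' @return A `crystallotype_preset`, or a named list of the two.
#' @export
default_presets <- function(which = c("all", "ordered", "disordered")) {
  which <- match.arg(which)
  ordered <- crystallotype_preset("ordered", 27, 7, 131, 24, 20, 30)
  disordered <- crystallotype_preset("disordered", 25, 8, 186, 81, 30, 40)
  switch(which,
         all = list(ordered = ordered, disordered = disordered),
         ordered = ordered,
         disordered = disordered)
}

#' @export
print.crystallotype_preset <- function(x, ...) {
  cat(sprintf("Crystallotype preset '%s'\n", x$name))
  cat(sprintf("  crystal thickness: %g +/- %g nm (n = %g)\n",
              x$crystal_thickness_mean, x$crystal_thickness_sd, x$n_crystal))
  cat(sprintf("  cytoplasm spacing: %g +/- %g nm (n = %g)\n",
              x$cytoplasm_mean, x$cytoplasm_sd, x$n_cytoplasm))
  cat(sprintf("  crystal layers:    %d-%d\n",
              x$layer_count_min, x$layer_count_max))
  invisible(x)
}

is_preset <- function(x) inherits(x, "crystallotype_preset")
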