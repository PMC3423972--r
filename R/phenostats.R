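#' Molar mass of thiabendazole
#'
#' 201.25 g/mol, from the formula C10H7N3S implied by the chemical name
#' 4-(1H-1,3-benzodiazol-2-yl)-1,3-thiazole:
#' 10*12.011 + 7*1.008 + 3*14.007 + 32.06 = 201.25.
#'
#' @export
tbz_molar_mass <- 201.25

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test: with margins fixed, the two-sided p-value is the
#' sum of hypergeometric probabilities of all tables as or less probable than
#' the observed one (the "as-or-less-probable" rule, applied with relative
#' tolerance 1e-7 in the comparison; mid-p is not used). Rows are treatment
#' groups, columns phenotype present/absent.
#'
#' @param a Either the top-left count, or a 2x2 integer matrix.
#' @param b,c,d Remaining counts (row-wise) when `a` is scalar.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(6, 2, 0, 9)  # ectopic-vessel phenotype table, ~0.00226
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2, 2))) stop("matrix must be 2x2", call. = FALSE)
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  r1 <- a + b
  c1 <- a + c
  n <- sum(counts)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- probs[xs == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' Tumor volume from caliper measurements
#'
#' `Volume = width^2 * length / 2` in cubic millimetres. If a width exceeds
#' its paired length the two are swapped (with a note), enforcing
#' `width <= length`.
#'
#' @param width,length Caliper measurements in mm (vectors of equal length).
#' @return Volume(s) in mm^3.
#' @export
tumor_volume <- function(width, length) {
  if (base::length(width) != base::length(length)) {
    stop("'width' and 'length' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(width)) || any(!is.finite(length)) ||
      any(width <= 0) || any(length <= 0)) {
    stop("measurements must be positive and finite", call. = FALSE)
  }
  swap <- width > length
  if (any(swap)) {
    message(sum(swap), " measurement(s) had width > length; swapped")
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  width^2 * length / 2
}

#' Scratch-wound closure ratio
#'
#' Fraction of the initial cell-free area closed after the incubation:
#' `(area_0 - area_t) / area_0`. If the wound grew (`area_t > area_0`) a
#' negative closure is reported, with a note, rather than clamped.
#'
#' @param area_0 Cell-free area at time zero (must be positive).
#' @param area_t Cell-free area at the later time point (nonnegative).
#' @return Closure fraction (at most 1; negative if the wound grew).
#' @export
wound_closure_ratio <- function(area_0, area_t) {
  if (any(!is.finite(area_0)) || any(area_0 <= 0)) {
    stop("'area_0' must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(area_t)) || any(area_t < 0)) {
    stop("'area_t' must be nonnegative and finite", call. = FALSE)
  }
  if (any(area_t > area_0)) {
    message("wound area increased (area_t > area_0); reporting negative closure")
  }
  (area_0 - area_t) / area_0
}

#' Dose equivalence conversion
#'
#' Converts an administered mass to body-mass-normalized dose and its molar
#' equivalent: `mg_per_kg = mass_mg / (body_mass_g / 1000)` and
#' `umol_per_kg = mg_per_kg / molar_mass * 1000`. Under the default density
#' assumption of 1 kg body mass per litre, µmol/kg is also reported as the
#' µM-equivalent concentration (e.g. 1 mg in a 20 g mouse is 50 mg/kg, about
#' 250 µM-equivalent for thiabendazole).
#'
#' @param mass_mg Administered mass in mg.
#' @param body_mass_g Body mass in g.
#' @param molar_mass Molar mass in g/mol; defaults to [tbz_molar_mass].
#' @param density Body density assumption in kg/L (default 1).
#' @return List with `mg_per_kg`, `umol_per_kg` and `uM_equivalent`.
#' @export
dose_convert <- function(mass_mg, body_mass_g, molar_mass = tbz_molar_mass,
                         density = 1) {
  vals <- c(mass_mg, body_mass_g, molar_mass, density)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all dose parameters must be positive and finite", call. = FALSE)
  }
  mg_per_kg <- mass_mg / (body_mass_g / 1000)
  umol_per_kg <- mg_per_kg / molar_mass * 1000
  list(mg_per_kg = mg_per_kg,
       umol_per_kg = umol_per_kg,
       uM_equivalent = umol_per_kg * density)
}

#' Stained area above a fluorescence threshold
#'
#' Microvessel-density quantification: the fraction (and count) of pixels
#' whose intensity is strictly above the threshold, as used for area of
#' endothelial (PECAM-1) staining in tumor sections.
#'
#' @param image Nonnegative numeric matrix of intensities.
#' @param threshold Finite intensity threshold (strict `>` comparison).
#' @return List with `fraction`, `n_above` and `n_pixels`.
#' @export
vessel_area_fraction <- function(image, threshold) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0) {
    stop("'image' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("intensities must be nonnegative and finite", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold)) {
    stop("'threshold' must be a finite number", call. = FALSE)
  }
  n_above <- sum(image > threshold)
  list(fraction = n_above / length(image),
       n_above = n_above,
       n_pixels = length(image))
}
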