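## Pluggable echocardiographic Z-score nomograms.
##
## A nomogram maps body-surface area to the expected vessel diameter and its
## population SD; the Z-score of an observed diameter is
## (observed - expected) / SD.  Coefficient sets are configuration, not
## doctrine: users supply their preferred pediatric reference via
## nomogram() or read_nomogram().

#' Construct a Z-score nomogram
#'
#' Linear-in-BSA mean model with constant SD:
#' `expected_mm = mean_intercept + mean_bsa * bsa_m2`.
#'
#' @param name Identifier for reports.
#' @param vessel `"sinus_of_valsalva"` or `"pulmonary_artery"`.
#' @param mean_intercept,mean_bsa Mean-model coefficients (mm, mm per
#'   m\eqn{^2}).
#' @param sd_mm Constant population SD (mm, > 0).
#' @param bsa_range Admissible BSA range (m\eqn{^2}); Z-scores outside it
#'   are refused.
#' @return Object of class `nomogram`.
#' @export
nomogram <- function(name, vessel = c("sinus_of_valsalva",
                                      "pulmonary_artery"),
                     mean_intercept, mean_bsa, sd_mm,
                     bsa_range = c(0.2, 2)) {
  vessel <- match.arg(vessel)
  stopifnot(is.numeric(mean_intercept), is.numeric(mean_bsa),
            is.numeric(sd_mm), sd_mm > 0,
            length(bsa_range) == 2, bsa_range[1] < bsa_range[2])
  expected_at <- function(b) mean_intercept + mean_bsa * b
  if (any(expected_at(bsa_range) <= 0)) {
    stop("nomogram mean must be strictly positive over the admissible ",
         "BSA range", call. = FALSE)
  }
  structure(
    list(name = name, vessel = vessel,
         mean_intercept = mean_intercept, mean_bsa = mean_bsa,
         sd_mm = sd_mm, bsa_range = bsa_range),
    class = "nomogram"
  )
}

#' @export
print.nomogram <- function(x, ...) {
  cat("Nomogram '", x$name, "' (", x$vessel, ")\n", sep = "")
  cat("  expected diameter (mm) = ", x$mean_intercept, " + ", x$mean_bsa,
      " * BSA;  SD = ", x$sd_mm, " mm\n", sep = "")
  cat("  admissible BSA: [", x$bsa_range[1], ", ", x$bsa_range[2], "] m^2\n",
      sep = "")
  invisible(x)
}

#' Bundled default sinus-of-Valsalva nomogram
#'
#' Pediatric aortic-root (sinus of Valsalva) reference of Roman et al.
#' (Am J Cardiol 1989;64:507-512): expected diameter in children
#' `1.02 + 0.98 * BSA` cm with a residual SD of 0.18 cm, carried here in mm.
#'
#' @return A `nomogram` object.
#' @export
default_sv_nomogram <- function() {
  nomogram("roman1989_children", "sinus_of_valsalva",
           mean_intercept = 10.2, mean_bsa = 9.8, sd_mm = 1.8,
           bsa_range = c(0.2, 2))
}

#' Bundled default pulmonary-artery nomogram
#'
#' A *synthetic* example coefficient set (linear in BSA) provided so the
#' pipeline runs end-to-end; it is not a published reference.  Users
#' assessing real patients should load their preferred pediatric
#' pulmonary-artery reference with [read_nomogram()] or [nomogram()].
#'
#' @return A `nomogram` object named `"pa_synthetic_linear"`.
#' @export
default_pa_nomogram <- function() {
  nomogram("pa_synthetic_linear", "pulmonary_artery",
           mean_intercept = 8.9, mean_bsa = 9.7, sd_mm = 1.9,
           bsa_range = c(0.2, 2))
}

#' Read a nomogram from a YAML config file
#'
#' Schema (all keys required): `name`, `vessel`, `mean: {intercept, bsa}`,
#' `sd_mm`, `bsa_range: [lo, hi]`.
#'
#' @param path YAML file path.
#' @return A `nomogram` object.
#' @export
read_nomogram <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "vessel", "mean", "sd_mm", "bsa_range")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    stop("nomogram config missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nomogram(cfg$name, cfg$vessel,
           mean_intercept = cfg$mean$intercept, mean_bsa = cfg$mean$bsa,
           sd_mm = cfg$sd_mm, bsa_range = as.numeric(cfg$bsa_range))
}

#' Z-score of an observed diameter
#'
#' `(observed - expected) / SD` under the given nomogram; strictly
#' increasing in the diameter at fixed covariates.
#'
#' @param nom A `nomogram`.
#' @param diameter_mm Observed diameter(s), mm, > 0.
#' @param bsa_m2 Body-surface area(s), m\eqn{^2}, within the nomogram's
#'   admissible range.
#' @return Numeric Z-score(s).
#' @export
zscore <- function(nom, diameter_mm, bsa_m2) {
  stopifnot(inherits(nom, "nomogram"))
  if (any(diameter_mm <= 0, na.rm = TRUE)) {
    stop("diameter_mm must be strictly positive", call. = FALSE)
  }
  out_lo <- !is.na(bsa_m2) & bsa_m2 < nom$bsa_range[1]
  out_hi <- !is.na(bsa_m2) & bsa_m2 > nom$bsa_range[2]
  if (any(out_lo | out_hi)) {
    stop("BSA out of the admissible range [", nom$bsa_range[1], ", ",
         nom$bsa_range[2], "] m^2 for nomogram '", nom$name, "'",
         call. = FALSE)
  }
  expected <- nom$mean_intercept + nom$mean_bsa * bsa_m2
  (diameter_mm - expected) / nom$sd_mm
}

#' Dilatation flag from a Z-score
#'
#' @param z Z-score(s).
#' @param threshold Dilatation threshold, inclusive (default 2.0, the
#'   convention of the revised Ghent criteria).
#' @return Logical: `z >= threshold`.
#' @export
is_dilated <- function(z, threshold = 2) {
  z >= threshold
}

#' Body-surface area (Mosteller)
#'
#' `sqrt(height_cm * weight_kg / 3600)` m\eqn{^2}.
#' @param height_cm,weight_kg Positive reals.
#' @return BSA in m\eqn{^2}.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  stopifnot(all(height_cm > 0), all(weight_kg > 0))
  sqrt(height_cm * weight_kg / 3600)
}

#' Body-surface area (Du Bois)
#'
#' `0.007184 * height_cm^0.725 * weight_kg^0.425` m\eqn{^2}.
#' @inheritParams bsa_mosteller
#' @return BSA in m\eqn{^2}.
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  stopifnot(all(height_cm > 0), all(weight_kg > 0))
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Resolve vessel dilatation for every record
#'
#' Contract: a direct `sv_dilated`/`pa_dilated` flag, when present,
#' overrides the nomogram, which is then never consulted for that record.
#' Records without a flag need both a diameter and a BSA; otherwise the
#' stratification is uncomputable and an error names the offending rows
#' (absent data are never defaulted to "not dilated").
#'
#' @param cohort Cohort data.frame.
#' @param vessel `"sv"` or `"pa"`.
#' @param nomogram A `nomogram`, or `NULL` for the bundled default of the
#'   vessel.
#' @param threshold Z-score threshold (inclusive).
#' @return Logical vector, one flag per record.
#' @export
resolve_dilation <- function(cohort, vessel = c("sv", "pa"), nomogram = NULL,
                             threshold = 2) {
  vessel <- match.arg(vessel)
  flag <- cohort[[paste0(vessel, "_dilated")]]
  diam <- cohort[[paste0(vessel, "_diameter_mm")]]
  need <- is.na(flag)
  out <- flag
  if (any(need)) {
    computable <- need & !is.na(diam) & !is.na(cohort$bsa_m2)
    bad <- need & !computable
    if (any(bad)) {
      stop(toupper(vessel), " dilatation unresolvable for row(s) ",
           paste(which(bad), collapse = ", "),
           ": no direct flag and no (diameter, BSA) pair", call. = FALSE)
    }
    if (is.null(nomogram)) {
      nomogram <- if (vessel == "sv") default_sv_nomogram()
                  else default_pa_nomogram()
    }
    idx <- which(computable)
    out[idx] <- is_dilated(zscore(nomogram, diam[idx], cohort$bsa_m2[idx]),
                           threshold)
  }
  out
}
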