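#' Energy density of a liquid reward from its macronutrient concentrations
#'
#' Applies the standard Atwater conversion factors (9, 4 and 4 kcal per gram
#' of fat, carbohydrate and protein) to concentrations expressed in
#' g/100 mL, returning kcal/mL.
#'
#' @param fat,sugar,protein Macronutrient concentrations in g/100 mL.
#' @return Energy density in kcal/mL.
#' @examples
#' atwater_energy_density(fat = 3.6, sugar = 0, protein = 3.4)
#' @export
atwater_energy_density <- function(fat, sugar, protein = 0) {
  (9 * fat + 4 * sugar + 4 * protein) / 100
}

#' Construct a stimulus table
#'
#' A stimulus table holds one row per liquid reward with its nutrient
#' concentrations, flavor, ordinal fat/sugar levels, energy density and
#' (optionally) measured texture parameters: viscosity (mPa s) and the
#' water-normalized coefficient of sliding friction (CSF).
#'
#' @param id Character stimulus identifiers (unique).
#' @param fat,sugar,protein Concentrations in g/100 mL (non-negative).
#' @param flavor Flavor label, recycled.
#' @param fat_level,sugar_level Optional ordinal labels (`"low"`/`"high"`).
#' @param energy_density Optional kcal/mL; derived by
#'   [atwater_energy_density()] when missing.
#' @param viscosity,csf Optional texture measurements; `csf` must be positive
#'   where present.
#' @return A `data.frame` of class `"stimulus_table"`. Pairs of stimuli whose
#'   energy densities differ by less than `1e-6` kcal/mL are recorded in the
#'   `"isocaloric_pairs"` attribute.
#' @export
stimulus_table <- function(id, fat, sugar, protein = 0, flavor = "peach",
                           fat_level = NULL, sugar_level = NULL,
                           energy_density = NULL, viscosity = NULL,
                           csf = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate stimulus id: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  n <- length(id)
  fat <- rep_len(as.numeric(fat), n)
  sugar <- rep_len(as.numeric(sugar), n)
  protein <- rep_len(as.numeric(protein), n)
  if (any(c(fat, sugar, protein) < 0)) stop("negative nutrient concentration")
  if (is.null(energy_density)) {
    energy_density <- atwater_energy_density(fat, sugar, protein)
  } else {
    energy_density <- rep_len(as.numeric(energy_density), n)
    miss <- is.na(energy_density)
    energy_density[miss] <- atwater_energy_density(fat[miss], sugar[miss],
                                                   protein[miss])
  }
  out <- data.frame(
    id = id, flavor = rep_len(as.character(flavor), n),
    fat = fat, sugar = sugar, protein = protein,
    fat_level = if (is.null(fat_level)) ordinal_level(fat) else
      rep_len(as.character(fat_level), n),
    sugar_level = if (is.null(sugar_level)) ordinal_level(sugar) else
      rep_len(as.character(sugar_level), n),
    energy_density = energy_density,
    viscosity = if (is.null(viscosity)) NA_real_ else
      rep_len(as.numeric(viscosity), n),
    csf = if (is.null(csf)) NA_real_ else rep_len(as.numeric(csf), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$csf) & out$csf <= 0)) stop("csf must be positive")
  class(out) <- c("stimulus_table", "data.frame")
  attr(out, "isocaloric_pairs") <- isocaloric_pairs(out)
  out
}

ordinal_level <- function(x) {
  if (length(unique(x)) <= 1) return(rep("low", length(x)))
  ifelse(x > mean(range(x)), "high", "low")
}

isocaloric_pairs <- function(stimuli, tol = 1e-6) {
  n <- nrow(stimuli)
  if (n < 2) return(data.frame(a = character(), b = character()))
  idx <- utils::combn(n, 2)
  keep <- abs(stimuli$energy_density[idx[1, ]] -
                stimuli$energy_density[idx[2, ]]) < tol
  data.frame(a = stimuli$id[idx[1, keep]], b = stimuli$id[idx[2, keep]],
             stringsAsFactors = FALSE)
}

#' Build the 2 x 2 fat-by-sugar factorial stimulus set
#'
#' Creates the four liquid rewards of the factorial design: LFLS (low-fat
#' low-sugar), HFLS, LFHS and HFHS, with constant protein. When the levels
#' satisfy \eqn{9\,\Delta fat = 4\,\Delta sugar} the HFLS and LFHS rewards
#' are isocaloric; the defaults (skimmed- vs whole-milk fat, lactose vs
#' added sugar) are chosen to meet that constraint exactly.
#'
#' @param fat_levels,sugar_levels Length-2 numeric vectors (low, high) in
#'   g/100 mL, strictly increasing.
#' @param protein Protein concentration g/100 mL, constant across stimuli.
#' @param flavor Flavor label for all four stimuli.
#' @param prefix Optional prefix prepended to the ids.
#' @return A [stimulus_table()] with rows LFLS, HFLS, LFHS, HFHS.
#' @examples
#' stim <- make_factorial_stimuli()
#' stim$energy_density  # HFLS and LFHS match
#' @export
make_factorial_stimuli <- function(fat_levels = c(0.1, 3.6),
                                   sugar_levels = c(4.7, 12.575),
                                   protein = 3.4, flavor = "peach",
                                   prefix = "") {
  if (length(fat_levels) != 2 || length(sugar_levels) != 2 ||
      diff(fat_levels) <= 0 || diff(sugar_levels) <= 0) {
    stop("fat_levels and sugar_levels must each be ordered (low, high)")
  }
  stimulus_table(
    id = paste0(prefix, c("LFLS", "HFLS", "LFHS", "HFHS")),
    fat = fat_levels[c(1, 2, 1, 2)],
    sugar = sugar_levels[c(1, 1, 2, 2)],
    protein = protein, flavor = flavor,
    fat_level = c("low", "high", "low", "high"),
    sugar_level = c("low", "low", "high", "high")
  )
}

#' Affine fat-to-texture model
#'
#' Describes viscosity and CSF as affine functions of fat concentration with
#' per-stimulus Gaussian noise, mirroring the empirical pattern that fat
#' thickens (positive viscosity slope) and lubricates (negative CSF slope)
#' a liquid. The CSF intercept of 1 corresponds to the water-normalized
#' baseline.
#'
#' @param visc_intercept,visc_slope Viscosity intercept (mPa s) and slope per
#'   g/100 mL fat; slope must be non-negative.
#' @param csf_intercept,csf_slope CSF intercept (water-normalized) and slope
#'   per g/100 mL fat; slope must be non-positive.
#' @param visc_noise_sd,csf_noise_sd Per-stimulus noise standard deviations.
#' @return A list of class `"texture_model"`.
#' @export
texture_model <- function(visc_intercept = 1.2, visc_slope = 0.3,
                          csf_intercept = 1.0, csf_slope = -0.06,
                          visc_noise_sd = 0.15, csf_noise_sd = 0.03) {
  if (visc_slope < 0) stop("viscosity slope must be >= 0")
  if (csf_slope > 0) stop("csf slope must be <= 0 (high fat is slippery)")
  structure(list(visc_intercept = visc_intercept, visc_slope = visc_slope,
                 csf_intercept = csf_intercept, csf_slope = csf_slope,
                 visc_noise_sd = visc_noise_sd, csf_noise_sd = csf_noise_sd),
            class = "texture_model")
}

#' Attach simulated texture measurements to a stimulus table
#'
#' Fills the `viscosity` and `csf` columns from an affine fat-to-texture
#' model plus per-stimulus noise; reproducible for a fixed seed. CSF values
#' are floored just above zero so the water-normalized coefficient stays
#' positive.
#'
#' @param stimuli A [stimulus_table()].
#' @param model A [texture_model()].
#' @param seed Integer seed for the measurement noise.
#' @return The stimulus table with `viscosity` and `csf` filled.
#' @export
apply_texture <- function(stimuli, model = texture_model(), seed = 1) {
  stopifnot(inherits(model, "texture_model"))
  set.seed(seed)
  n <- nrow(stimuli)
  stimuli$viscosity <- model$visc_intercept + model$visc_slope * stimuli$fat +
    stats::rnorm(n, 0, model$visc_noise_sd)
  stimuli$csf <- model$csf_intercept + model$csf_slope * stimuli$fat +
    stats::rnorm(n, 0, model$csf_noise_sd)
  stimuli$viscosity <- pmax(stimuli$viscosity, 1e-3)
  stimuli$csf <- pmax(stimuli$csf, 1e-3)
  stimuli
}

#' Read a stimulus table from CSV or JSON
#'
#' Accepts a delimited file (header columns `id, fat, sugar, protein, ...`)
#' or a JSON array of stimulus records. Missing energy densities are filled
#' from the Atwater formula; duplicate ids and negative concentrations are
#' errors.
#'
#' @param path File path; format chosen by extension (`.json` vs delimited).
#' @return A [stimulus_table()].
#' @seealso [write_stimuli()]
#' @export
read_stimuli <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("id", "fat", "sugar")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("stimulus file missing required column: ",
                         paste(miss, collapse = ", "))
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else NULL
  stimulus_table(
    id = raw$id, fat = raw$fat, sugar = raw$sugar,
    protein = if (is.null(grab("protein"))) 0 else raw$protein,
    flavor = if (is.null(grab("flavor"))) "unknown" else raw$flavor,
    fat_level = grab("fat_level"), sugar_level = grab("sugar_level"),
    energy_density = grab("energy_density"),
    viscosity = grab("viscosity"), csf = grab("csf")
  )
}

#' Write a stimulus table to CSV or JSON
#'
#' @param stimuli A [stimulus_table()].
#' @param path Destination; `.json` writes a JSON array, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_stimuli <- function(stimuli, path) {
  df <- as.data.frame(stimuli)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.stimulus_table <- function(x, ...) {
  cat("Stimulus table:", nrow(x), "stimuli\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  iso <- attr(x, "isocaloric_pairs")
  if (!is.null(iso) && nrow(iso)) {
    cat("Isocaloric pairs:",
        paste(iso$a, iso$b, sep = "/", collapse = ", "), "\n")
  }
  invisible(x)
}
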