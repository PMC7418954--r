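#' Names of the ten interlandmark laryngeal measurements
#'
#' The canonical measurement set, in the conventional order from most to
#' least variable across species. Each is a Euclidean distance (mm) between
#' two of the 14 anatomical landmarks (vocal fold length averages the right
#' and left vocal-process distances).
#'
#' @return Character vector of length 10.
#' @export
measurement_names <- function() {
  c(
    "ventral_cricoid_height", "larynx_height", "ventral_thyroid_height",
    "vocal_fold_length", "crico_thyroid_distance", "dorsal_cricoid_height",
    "apical_cricoid_depth", "basal_cricoid_depth", "basal_cricoid_width",
    "dorsal_thyroid_width"
  )
}

# landmark index pairs defining each measurement; vocal fold length is the
# mean of 9-12 and 9-13 and is handled specially
.measurement_pairs <- function() {
  list(
    ventral_cricoid_height = c(1, 2),
    larynx_height = c(1, 14),
    ventral_thyroid_height = c(7, 8),
    vocal_fold_length = NA, # (|9-12| + |9-13|) / 2
    crico_thyroid_distance = c(4, 9),
    dorsal_cricoid_height = c(3, 4),
    apical_cricoid_depth = c(2, 4),
    basal_cricoid_depth = c(1, 3),
    basal_cricoid_width = c(5, 6),
    dorsal_thyroid_width = c(10, 11)
  )
}

#' Column dictionary for specimen tables
#'
#' Documents the CSV schema the pipeline reads and the simulator writes.
#' One row per species (one specimen per species); units are fixed:
#' lengths mm, masses g, ages years, F0 Hz.
#'
#' @return A tibble with columns `column`, `type`, `required`, `description`.
#' @export
specimen_dictionary <- function() {
  tibble(
    column = c(
      "species", "clade", measurement_names(), "body_length_mm",
      "body_mass_g", "specimen_sex", "age_at_death_y", "max_lifespan_y",
      "male_mass_g", "female_mass_g", "mean_f0_hz", "group_size"
    ),
    type = c(
      "character", "character", rep("numeric", 10), "numeric",
      "numeric", "character (M/F/unknown)", "numeric", "numeric",
      "numeric", "numeric", "numeric", "numeric"
    ),
    required = c(
      TRUE, TRUE, rep(FALSE, 10), TRUE,
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE
    ),
    description = c(
      "species label (spaces or underscores)",
      "one of 'primate', 'carnivoran'",
      paste("interlandmark distance (mm):", gsub("_", " ", measurement_names())),
      "specimen body length, snout/crown to ischium (mm)",
      "specimen body mass (g)",
      "sex of the measured specimen",
      "specimen age at death (years)",
      "species maximum recorded lifespan (years)",
      "species average male mass (g)",
      "species average female mass (g)",
      "species mean call fundamental frequency (Hz)",
      "species mean social group size (>= 1)"
    )
  )
}

#' Read and validate a specimen table
#'
#' Reads a CSV in the [specimen_dictionary()] schema (either the 10
#' measurement columns, or landmark coordinates via a separate landmark
#' file fed to [landmark_distances()]), normalizes species labels and
#' validates ranges.
#'
#' @param path CSV file path.
#' @param synonyms Optional synonym map, see [normalize_labels()].
#' @return A validated tibble.
#' @export
read_specimen_table <- function(path, synonyms = NULL) {
  if (!file.exists(path)) abort(paste0("specimen table not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  inform(sprintf("read %d specimen rows from %s", nrow(df), path))
  validate_specimen_table(as_tibble(df), synonyms = synonyms)
}

#' @rdname read_specimen_table
#' @param data A data frame to validate in place.
#' @export
validate_specimen_table <- function(data, synonyms = NULL) {
  data <- as_tibble(data)
  for (col in c("species", "clade")) {
    if (!col %in% names(data)) abort(paste0("missing required column: ", col))
  }
  data$species <- normalize_labels(data$species, synonyms)
  if (anyDuplicated(data$species)) {
    abort(paste0(
      "duplicate species: ",
      paste(unique(data$species[duplicated(data$species)]), collapse = ", ")
    ))
  }
  bad_clade <- setdiff(unique(data$clade), c("primate", "carnivoran"))
  if (length(bad_clade)) {
    abort(paste0("unknown clade value(s): ", paste(bad_clade, collapse = ", ")))
  }
  meas <- intersect(measurement_names(), names(data))
  if (length(meas) == 0 && !"body_length_mm" %in% names(data)) {
    abort("table has neither measurement columns nor body_length_mm")
  }
  pos_cols <- c(
    meas, "body_length_mm", "body_mass_g", "male_mass_g",
    "female_mass_g", "mean_f0_hz", "max_lifespan_y", "age_at_death_y"
  )
  for (col in intersect(pos_cols, names(data))) {
    v <- data[[col]]
    if (any(!is.na(v) & v <= 0)) {
      abort(paste0("column ", col, " has non-positive values"))
    }
  }
  if ("group_size" %in% names(data)) {
    if (any(!is.na(data$group_size) & data$group_size < 1)) {
      abort("group_size must be >= 1")
    }
  }
  if (all(c("age_at_death_y", "max_lifespan_y") %in% names(data))) {
    ra <- data$age_at_death_y / data$max_lifespan_y
    bad <- !is.na(ra) & (ra <= 0 | ra > 1.5)
    if (any(bad)) {
      abort(paste0(
        "relative age (age_at_death_y / max_lifespan_y) outside (0, 1.5] for: ",
        paste(data$species[bad], collapse = ", ")
      ))
    }
  }
  if ("specimen_sex" %in% names(data)) {
    data$specimen_sex[is.na(data$specimen_sex)] <- "unknown"
    bad <- setdiff(unique(data$specimen_sex), c("M", "F", "unknown"))
    if (length(bad)) {
      abort(paste0("specimen_sex must be M/F/unknown, got: ", paste(bad, collapse = ", ")))
    }
  }
  data
}
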