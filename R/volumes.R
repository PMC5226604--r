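#' Construct a per-animal tumor-volume series
#'
#' Long-format records of tumor volume (mm^3) over time for a two-arm PDX
#' trial. Validation enforces the trial-design invariants: each animal
#' belongs to exactly one model and one arm, no duplicated
#' `(animal, day)` measurement, strictly positive volumes, and a day-0
#' baseline record for every animal.
#'
#' @param df data.frame with columns `model`, `animal`, `arm`
#'   (`"control"`/`"treated"`), `day` (integer >= 0), `volume` (mm^3 > 0).
#' @return the validated data.frame with class `volume_series`.
#' @export
volume_series <- function(df) {
  req <- c("model", "animal", "arm", "day", "volume")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L)
    abort_format(sprintf("volume table missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df)[req]
  df$model <- as.character(df$model)
  df$animal <- as.character(df$animal)
  df$arm <- tolower(as.character(df$arm))
  bad_arm <- setdiff(unique(df$arm), c("control", "treated"))
  if (length(bad_arm) > 0L)
    abort_validation(sprintf("unknown arm label(s): %s",
                             paste(bad_arm, collapse = ", ")))
  if (nrow(df) == 0L) abort_validation("empty volume series")
  df$day <- as.integer(df$day)
  df$volume <- as.numeric(df$volume)
  if (anyNA(df$day) || any(df$day < 0L))
    abort_validation("`day` must be integer >= 0")
  if (anyNA(df$volume) || any(df$volume <= 0))
    abort_validation("`volume` must be > 0 mm^3")
  if (anyDuplicated(df[c("animal", "day")]))
    abort_validation("duplicated (animal, day) measurement")
  arms_per_animal <- tapply(df$arm, df$animal, function(a) length(unique(a)))
  if (any(arms_per_animal > 1L))
    abort_validation(sprintf(
      "animal(s) recorded in more than one arm: %s",
      paste(names(arms_per_animal)[arms_per_animal > 1L], collapse = ", ")))
  models_per_animal <- tapply(df$model, df$animal,
                              function(m) length(unique(m)))
  if (any(models_per_animal > 1L))
    abort_validation(sprintf(
      "animal(s) recorded in more than one model: %s",
      paste(names(models_per_animal)[models_per_animal > 1L], collapse = ", ")))
  has_baseline <- tapply(df$day, df$animal, function(d) any(d == 0L))
  if (!all(has_baseline))
    abort_validation(sprintf(
      "animal(s) missing a day-0 baseline record: %s",
      paste(names(has_baseline)[!has_baseline], collapse = ", ")))
  class(df) <- c("volume_series", "data.frame")
  df
}

#' Read a tumor-volume series
#'
#' @param path delimited long-format file with columns
#'   `model,animal,arm,day,volume`.
#' @return a [volume_series()].
#' @export
read_volumes <- function(path) {
  if (!file.exists(path))
    abort_validation(sprintf("volume file not found: %s", path))
  volume_series(read_any_delim(path))
}

#' Write a tumor-volume series
#' @param volumes a [volume_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_volumes <- function(volumes, path) {
  write.table(as.data.frame(volumes), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
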