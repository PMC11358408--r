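#' Read a per-sample measurement table
#'
#' Reads the delimited sample table (CSV, UTF-8, header row) with the
#' mandatory identification and mass columns plus one column per
#' measured parameter. Unparseable numeric cells become `NA` with a
#' message; rows are retained.
#'
#' @param path Path to the CSV file.
#' @param required Columns that must be present (default: `sample_id`,
#'   `species`, `time_h`, `m_f`, `m_a`).
#' @return A data.frame; numeric columns coerced, parameter columns kept.
#' @export
read_sample_table <- function(path,
                              required = c("sample_id", "species", "time_h",
                                           "m_f", "m_a")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop(sprintf("sample table %s is missing mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  char_cols <- intersect(c("sample_id", "species"), names(raw))
  for (col in setdiff(names(raw), char_cols)) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- sum(!is.na(v) & is.na(num))
    if (bad > 0)
      message(sprintf("column %s: %d unparseable cell(s) set to NA", col, bad))
    raw[[col]] <- num
  }
  message(sprintf("read %d sample row(s) from %s", nrow(raw), path))
  raw
}

#' Write a per-sample measurement table
#'
#' @param samples Data.frame as produced by [simulate_dataset()]'s
#'   `samples` component or read by [read_sample_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Read reflectance spectra from a delimited file
#'
#' Accepts two layouts: *long* form with columns `sample_id`, `side`,
#' `mode`, `wavelength_nm`, `reflectance`; or *wide* form whose first
#' column is `wavelength_nm` and every other column one sample (adaxial
#' diffusive assumed). Percent-scaled reflectance is auto-detected by
#' the spectrum constructor.
#'
#' @param path Path to the CSV file.
#' @return A named list of [reflectance_spectrum()] objects.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("sample_id", "wavelength_nm", "reflectance") %in% names(d))) {
    if (!"side" %in% names(d)) d$side <- "adaxial"
    if (!"mode" %in% names(d)) d$mode <- "diffusive"
    out <- lapply(split(d, d$sample_id), function(s) {
      s <- s[order(s$wavelength_nm), ]
      reflectance_spectrum(s$wavelength_nm, s$reflectance,
                           side = s$side[1L], mode = s$mode[1L],
                           sample_id = s$sample_id[1L])
    })
    return(out)
  }
  if (names(d)[1L] == "wavelength_nm") {
    ids <- names(d)[-1L]
    out <- lapply(ids, function(id)
      reflectance_spectrum(d$wavelength_nm, d[[id]], sample_id = id))
    names(out) <- ids
    return(out)
  }
  stop(sprintf("unrecognized spectra layout in %s", path), call. = FALSE)
}

#' Write spectra in long form
#'
#' @param spectra A list of [reflectance_spectrum()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(spectra, function(s)
    data.frame(sample_id = s$sample_id, side = s$side, mode = s$mode,
               wavelength_nm = s$wavelength_nm, reflectance = s$reflectance,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read protocol-level fluorescence records
#'
#' CSV with columns `sample_id`, `F0`, `FM`, `FMp1`, `FMpst`, `Fst`.
#'
#' @param path Path to the CSV file.
#' @return A list of [fluorescence_record()] objects.
#' @export
read_fluorescence_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "F0", "FM", "FMp1", "FMpst", "Fst")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop(sprintf("fluorescence table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  lapply(seq_len(nrow(d)), function(i)
    fluorescence_record(d$F0[i], d$FM[i], d$FMp1[i], d$FMpst[i], d$Fst[i],
                        sample_id = d$sample_id[i]))
}

round4 <- function(x) round(x, 4)

#' Write a ranked reliability table
#'
#' Human-facing columns are rounded to 4 decimal places (the convention
#' of printed coefficient tables); full-precision companions carry the
#' suffix `_full`.
#'
#' @param ranked A ranked table from [rank_parameters()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_results <- function(ranked, path) {
  out <- data.frame(rank = ranked$rank, species = ranked$species,
                    parameter = ranked$parameter, group = ranked$group,
                    n = ranked$n,
                    CR = round4(ranked$CR), CS = round4(ranked$CS),
                    CI = round4(ranked$CI), r2 = round4(ranked$r2),
                    reliable = ranked$reliable, tie = ranked$tie,
                    CR_full = ranked$CR, CS_full = ranked$CS,
                    CI_full = ranked$CI, r2_full = ranked$r2,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
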