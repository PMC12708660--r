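# File formats: EDF recordings, CSV hypnograms / IAT tables / behavior,
# TSV grids and maps, JSON configs and manifests.

#' Write a recording to EDF
#'
#' Minimal EDF writer (16-bit integer samples, 1-second data records,
#' physical units microvolts). Channels are scaled independently to their
#' physical range; the trailing partial second, if any, is dropped.
#'
#' @param rec A [new_recording()] object.
#' @param path Output file path.
#' @param patient,recording_id Free-text EDF header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "swabias") {
  data <- rec$data
  nch <- nrow(data)
  spr <- as.integer(round(rec$rate))
  n_rec <- floor(ncol(data) / spr)
  assert_that(n_rec >= 1, "recording shorter than one EDF record")
  data <- data[, seq_len(n_rec * spr), drop = FALSE]

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  pad <- function(x, w) {
    s <- substr(as.character(x), 1, w)
    sprintf(paste0("%-", w, "s"), s)
  }
  num <- function(x, w) pad(formatC(x, digits = 6, format = "g"), w)

  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeChar(paste0(s, collapse = ""), con,
                                 eos = NULL, useBytes = TRUE)
  wchar(pad("0", 8))
  wchar(pad(patient, 80))
  wchar(pad(recording_id, 80))
  wchar(pad("01.01.01", 8))
  wchar(pad("00.00.00", 8))
  wchar(pad(256 * (nch + 1), 8))
  wchar(pad("", 44))
  wchar(pad(n_rec, 8))
  wchar(pad(1, 8))
  wchar(pad(nch, 4))
  wchar(paste0(vapply(rec$channels, pad, "", w = 16), collapse = ""))
  wchar(strrep(" ", 80 * nch))               # transducer
  wchar(strrep(pad("uV", 8), nch))           # physical dimension
  wchar(paste0(vapply(pmin_, num, "", w = 8), collapse = ""))
  wchar(paste0(vapply(pmax_, num, "", w = 8), collapse = ""))
  wchar(strrep(pad(dmin, 8), nch))
  wchar(strrep(pad(dmax, 8), nch))
  wchar(strrep(" ", 80 * nch))               # prefiltering
  wchar(strrep(pad(spr, 8), nch))
  wchar(strrep(" ", 32 * nch))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- round((data[, cols, drop = FALSE] - pmin_) * scale) + dmin
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]; handles the plain continuous-EDF layout
#' (uniform sampling rate across signals).
#'
#' @param path EDF file path.
#' @return A [new_recording()] object.
#' @export
read_edf <- function(path) {
  hdr <- read_edf_header(path)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hdr$header_bytes)
  nch <- hdr$n_signals
  spr <- hdr$samples_per_record
  assert_that(length(unique(spr)) == 1,
              "mixed per-signal sampling rates are not supported")
  spr <- spr[1]
  raw <- readBin(con, integer(), n = hdr$n_records * nch * spr, size = 2,
                 endian = "little")
  if (length(raw) < hdr$n_records * nch * spr) {
    abort("EDF data shorter than header promises")
  }
  arr <- array(raw, c(spr, nch, hdr$n_records))
  data <- matrix(0, nch, spr * hdr$n_records)
  scale <- (hdr$phys_max - hdr$phys_min) / (hdr$dig_max - hdr$dig_min)
  for (ch in seq_len(nch)) {
    data[ch, ] <- as.vector(arr[, ch, ]) * scale[ch] +
      hdr$phys_min[ch] - hdr$dig_min[ch] * scale[ch]
  }
  new_recording(data, rate = spr / hdr$record_duration,
                channels = hdr$labels)
}

read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rchar(8))
  patient <- trimws(rchar(80))
  recording <- trimws(rchar(80))
  rchar(16)  # date, time
  header_bytes <- as.integer(rchar(8))
  rchar(44)
  n_records <- as.integer(rchar(8))
  record_duration <- as.numeric(rchar(8))
  ns <- as.integer(rchar(4))
  if (is.na(ns) || ns < 1 || is.na(header_bytes) ||
      header_bytes != 256 * (ns + 1)) {
    abort(sprintf("malformed EDF header in %s", path))
  }
  grab <- function(w) vapply(seq_len(ns), function(i) trimws(rchar(w)), "")
  labels <- grab(16)
  grab(80)
  grab(8)
  phys_min <- as.numeric(grab(8))
  phys_max <- as.numeric(grab(8))
  dig_min <- as.numeric(grab(8))
  dig_max <- as.numeric(grab(8))
  grab(80)
  spr <- as.integer(grab(8))
  list(version = version, patient = patient, recording = recording,
       header_bytes = header_bytes, n_records = n_records,
       record_duration = record_duration, n_signals = ns, labels = labels,
       phys_min = phys_min, phys_max = phys_max, dig_min = dig_min,
       dig_max = dig_max, samples_per_record = spr)
}

#' Hypnogram CSV round trip
#'
#' Columns `epoch_index`, `stage`; lights markers are stored as attributes in
#' two optional extra columns on the first row.
#'
#' @param hyp A [hypnogram()] object.
#' @param path CSV path.
#' @return `path` / a `swa_hypnogram`.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  df <- tibble(epoch_index = seq_along(hyp$stages), stage = hyp$stages,
               lights_off_epoch = NA_integer_, lights_on_epoch = NA_integer_)
  df$lights_off_epoch[1] <- hyp$lights_off_epoch
  df$lights_on_epoch[1] <- hyp$lights_on_epoch
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("epoch_index", "stage") %in% names(df)),
              "hypnogram CSV needs epoch_index and stage columns")
  df <- dplyr::arrange(df, .data$epoch_index)
  lo <- if ("lights_off_epoch" %in% names(df)) df$lights_off_epoch[1] else NA
  lon <- if ("lights_on_epoch" %in% names(df)) df$lights_on_epoch[1] else NA
  hypnogram(df$stage,
            lights_off_epoch = ifelse(is.na(lo), 1L, lo),
            lights_on_epoch = ifelse(is.na(lon), nrow(df), lon))
}

#' IAT trial table CSV round trip
#'
#' @param trials Tibble from [simulate_iat_trials()] (or same columns).
#' @param path CSV path.
#' @export
write_iat_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_iat_csv
#' @export
read_iat_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("block", "trial", "category", "rt_ms", "correct")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("IAT CSV lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  df
}

#' Voxel map / grid TSV round trips
#'
#' Maps serialize as TSV with columns `voxel`, `x_mm`, `y_mm`, `z_mm`,
#' `value`; grids without the value column. Subject x voxel matrices
#' serialize with a leading `subject` column, one voxel column per grid
#' point.
#'
#' @param map `swa_map` object (or grid tibble / matrix for the variants).
#' @param path TSV path.
#' @export
write_map_tsv <- function(map, path) {
  df <- tibble(voxel = map$grid$voxel, x_mm = map$grid$x, y_mm = map$grid$y,
               z_mm = map$grid$z, value = map$values)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_map_tsv
#' @param spacing_mm Spacing recorded in the rebuilt map.
#' @export
read_map_tsv <- function(path, spacing_mm = 5) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  grid <- tibble(voxel = df$voxel, x = df$x_mm, y = df$y_mm, z = df$z_mm)
  new_swa_map(df$value, grid, infer_spacing(grid) %||% spacing_mm)
}

#' @rdname write_map_tsv
#' @param grid Grid tibble with columns voxel, x, y, z.
#' @export
write_grid_tsv <- function(grid, path) {
  readr::write_tsv(tibble(voxel = grid$voxel, x_mm = grid$x, y_mm = grid$y,
                          z_mm = grid$z), path)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_grid_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble(voxel = df$voxel, x = df$x_mm, y = df$y_mm, z = df$z_mm)
}

#' @rdname write_map_tsv
#' @param maps Subject x voxel matrix.
#' @param subjects Subject identifiers (rows of `maps`).
#' @export
write_maps_matrix_tsv <- function(maps, subjects, path) {
  df <- as_tibble(as.data.frame(maps), .name_repair = "minimal")
  names(df) <- sprintf("v%04d", seq_len(ncol(maps)))
  readr::write_tsv(dplyr::bind_cols(tibble(subject = subjects), df), path)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_maps_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$subject
  m
}

#' Cohort configuration JSON round trip
#'
#' @param config A [cohort_config()] object.
#' @param path JSON path.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_config, lst[names(lst) %in% names(formals(cohort_config))])
}

#' Simulate a cohort and write it to disk as a study bundle
#'
#' Generates the full raw-data study layout: per subject an EDF night
#' recording, a hypnogram CSV and an IAT trial CSV, plus the voxel grid TSV,
#' the configuration JSON and a manifest tying everything together.
#'
#' @param config A [cohort_config()] object.
#' @param dir Output directory (created if needed).
#' @param lead_field Optional [generate_lead_field()]; default layout.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_study_bundle <- function(config, dir, lead_field = NULL) {
  lf <- lead_field %||% generate_lead_field()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  profiles <- cohort_source_profiles(cohort, lf, config)
  subjects <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject[i]
    night <- simulate_sleep_night(profiles[i, ], lf, config,
                                  seed = derive_seed(config$seed, 100 + i))
    # the latent trait is an absolute-D target; simulated bias is positive,
    # as for nearly all subjects in typical race-IAT samples
    trials <- simulate_iat_trials(cohort$behavior[i],
                                  derive_seed(config$seed, 200 + i),
                                  subject = id)
    edf <- file.path(dir, paste0(id, ".edf"))
    hyp <- file.path(dir, paste0(id, "_hypnogram.csv"))
    iat <- file.path(dir, paste0(id, "_iat.csv"))
    write_edf(night$recording, edf, patient = id)
    write_hypnogram_csv(night$hypnogram, hyp)
    write_iat_csv(trials, iat)
    subjects[[i]] <- list(id = id, edf = basename(edf),
                          hypnogram = basename(hyp), iat = basename(iat),
                          n_channels = nrow(night$recording$data))
  }
  write_grid_tsv(lf$grid, file.path(dir, "voxel_grid.tsv"))
  write_config_json(config, file.path(dir, "config.json"))
  manifest <- list(
    format = "swabias-study-bundle",
    version = as.character(utils::packageVersion("swabias")),
    config = "config.json",
    voxel_grid = "voxel_grid.tsv",
    seed = config$seed,
    subjects = subjects
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a study bundle
#'
#' Reads a manifest written by [write_study_bundle()] (or assembled by hand),
#' validating every subject's files: the EDF header must parse and match the
#' manifest channel count, hypnogram stages must be in the W/N1/N2/N3/REM
#' vocabulary, and the IAT CSV must have the required columns. Validation
#' problems are aggregated per subject rather than failing fast.
#'
#' @param manifest_path Path to `manifest.json`.
#' @return Object of class `swa_bundle`: list with `subjects` tibble (`id`,
#'   file paths, `ok`, `issue`), `config`, `grid`, `dir`, `seed`.
#' @export
load_study_bundle <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  config <- read_config_json(file.path(dir, man$config))
  grid <- read_grid_tsv(file.path(dir, man$voxel_grid))
  ids <- vapply(man$subjects, function(s) s$id, "")
  if (anyDuplicated(ids)) abort("duplicate subject ids in manifest")

  rows <- purrr::map(man$subjects, function(s) {
    files <- file.path(dir, c(s$edf, s$hypnogram, s$iat))
    issue <- character(0)
    missing <- !file.exists(files)
    if (any(missing)) {
      issue <- c(issue, sprintf("missing file(s): %s",
                                paste(basename(files[missing]), collapse = ", ")))
    } else {
      hdr <- tryCatch(read_edf_header(files[1]), error = conditionMessage)
      if (is.character(hdr)) {
        issue <- c(issue, sprintf("EDF: %s", hdr))
      } else if (!is.null(s$n_channels) && hdr$n_signals != s$n_channels) {
        issue <- c(issue, sprintf("EDF has %d channels, manifest says %d",
                                  hdr$n_signals, s$n_channels))
      }
      hyp <- tryCatch(read_hypnogram_csv(files[2]), error = conditionMessage)
      if (is.character(hyp)) issue <- c(issue, sprintf("hypnogram: %s", hyp))
      iat <- tryCatch(read_iat_csv(files[3]), error = conditionMessage)
      if (is.character(iat)) issue <- c(issue, sprintf("IAT: %s", iat))
    }
    tibble(id = s$id, edf = files[1], hypnogram = files[2], iat = files[3],
           ok = length(issue) == 0,
           issue = if (length(issue)) paste(issue, collapse = "; ")
                   else NA_character_)
  })
  structure(
    list(subjects = dplyr::bind_rows(rows), config = config, grid = grid,
         dir = dir, seed = man$seed),
    class = "swa_bundle"
  )
}

#' @export
print.swa_bundle <- function(x, ...) {
  cat(sprintf("<swa_bundle> %d subjects (%d valid) in %s\n",
              nrow(x$subjects), sum(x$subjects$ok), x$dir))
  invisible(x)
}
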