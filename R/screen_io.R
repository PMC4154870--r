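# Well-level screen tables, screen configuration, and plate-layout checks.

#' Well roles and stimuli recognised in screen tables
#'
#' `sample` wells carry library siRNAs; `neg_ctrl` are non-targeting
#' (Allstars-type) controls defining the null distribution; `pos_ctrl_pathway`
#' are pathway controls (p65-type) used as the NPI anchor; `pos_ctrl_receptor`
#' are receptor controls (NOD1-type) active only under the receptor-specific
#' stimulus; `tox_ctrl` are kill controls (PLK-type) used to monitor
#' transfection.
#'
#' @export
WELL_ROLES <- c("sample", "neg_ctrl", "pos_ctrl_pathway",
                "pos_ctrl_receptor", "tox_ctrl")

#' @rdname WELL_ROLES
#' @export
STIMULI <- c("TriDAP", "TNF", "mock")

#' Columns every well table must declare
#' @export
WELL_COLUMNS <- c("screen_id", "plate_id", "well", "replicate", "sirna_id",
                  "gene_id", "role", "stimulus", "readout_activity",
                  "readout_viability")

#' Build a screen configuration
#'
#' Central container for the plate design and every threshold the analysis
#' cascade applies, so no stage hard-codes a cut-off. Defaults reproduce the
#' standard arrayed-screen design: 384-well plates, four siRNAs per gene,
#' quadruplicate biological replicates, and the published exclusion and hit
#' thresholds.
#'
#' @param plate_format wells per plate (96 or 384).
#' @param sirnas_per_gene library siRNAs per gene (>= 1).
#' @param replicates biological replicates per siRNA.
#' @param control_layout named integer vector: minimum control wells per plate
#'   for each non-sample role.
#' @param thresholds named list of analysis thresholds:
#'   `plate_viability_hi` / `plate_viability_lo` bounds on the plate mean of
#'   the negative-control viability channel, `plate_viability_cv` maximum
#'   coefficient of variation (SD/mean) of that channel,
#'   `well_viability_frac` minimum well viability as a fraction of the plate's
#'   negative-control mean, `validation_sd` margin (in control SDs) of the
#'   validation/counter hit rule, `thp1_sd` and `thp1_strong_sd` margins of
#'   the secondary dual-readout screen rules.
#' @param zscore_scale robust scale used for per-plate z-scores:
#'   `"sample_mad"` (1.4826 x MAD of the plate's sample wells, default) or
#'   `"neg_sd"` (SD of the plate's negative controls).
#' @param npi_pos_role control role anchoring NPI = 1 (the pathway control by
#'   default; secondary screens may anchor on the receptor control).
#' @param validation_gene_rule gene-level validation call: `"strongest"`
#'   (gene is a hit if its best siRNA passes) or `"both"` (all scored siRNAs
#'   must pass).
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(plate_format = 384L,
                          sirnas_per_gene = 4L,
                          replicates = 4L,
                          control_layout = c(neg_ctrl = 8L,
                                             pos_ctrl_pathway = 4L,
                                             pos_ctrl_receptor = 4L,
                                             tox_ctrl = 4L),
                          thresholds = list(),
                          zscore_scale = c("sample_mad", "neg_sd"),
                          npi_pos_role = "pos_ctrl_pathway",
                          validation_gene_rule = c("strongest", "both"),
                          rng_seed = 1L) {
  default_thresholds <- list(plate_viability_hi = 2.5,
                             plate_viability_lo = 0.2,
                             plate_viability_cv = 0.50,
                             well_viability_frac = 0.40,
                             validation_sd = 2.0,
                             thp1_sd = 1.5,
                             thp1_strong_sd = 3.0)
  thresholds <- utils::modifyList(default_thresholds, as.list(thresholds))
  cfg <- structure(list(plate_format = as.integer(plate_format),
                        sirnas_per_gene = as.integer(sirnas_per_gene),
                        replicates = as.integer(replicates),
                        control_layout = control_layout,
                        thresholds = thresholds,
                        zscore_scale = match.arg(zscore_scale),
                        npi_pos_role = npi_pos_role,
                        validation_gene_rule = match.arg(validation_gene_rule),
                        rng_seed = as.integer(rng_seed)),
                   class = "screen_config")
  validate_config(cfg)
  cfg
}

#' Validate a screen configuration
#'
#' @param config a `screen_config`.
#' @return the configuration, invisibly; errors on violation.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  th <- config$thresholds
  if (!all(vapply(th, function(x) is.numeric(x) && x > 0, logical(1)))) {
    stop("all thresholds must be strictly positive", call. = FALSE)
  }
  if (th$plate_viability_lo >= th$plate_viability_hi) {
    stop("plate_viability_lo must be below plate_viability_hi", call. = FALSE)
  }
  if (config$sirnas_per_gene < 1L) {
    stop("sirnas_per_gene must be >= 1", call. = FALSE)
  }
  if (!config$plate_format %in% c(96L, 384L)) {
    stop("plate_format must be 96 or 384", call. = FALSE)
  }
  if (!config$npi_pos_role %in% setdiff(WELL_ROLES, c("sample", "neg_ctrl"))) {
    stop("npi_pos_role must be a positive-control role", call. = FALSE)
  }
  invisible(config)
}

#' Read / write a screen configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) by file extension. Only fields
#' present in the file override the package defaults.
#'
#' @param path file path.
#' @return `read_screen_config`: a `screen_config`.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  if (!is.null(raw$control_layout)) {
    raw$control_layout <- unlist(raw$control_layout)
  }
  do.call(screen_config, raw)
}

#' @rdname read_screen_config
#' @param config a `screen_config` to serialize.
#' @export
write_screen_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$control_layout <- as.list(out$control_layout)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yml = , yaml = yaml::write_yaml(out, path),
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}

# plate geometry ------------------------------------------------------------

plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
         "96"  = c(rows = 8L,  cols = 12L),
         "384" = c(rows = 16L, cols = 24L),
         stop("unsupported plate format: ", plate_format, call. = FALSE))
}

#' Parse 384/96-well coordinates
#'
#' Accepts the standard `"A01"`..`"P24"` convention case-insensitively, with
#' or without the zero pad. Returns the canonical upper-case zero-padded form.
#'
#' @param well character vector of well labels.
#' @param plate_format 96 or 384.
#' @return canonical well labels; `NA` where the label is malformed or out of
#'   range for the plate format.
#' @export
parse_well <- function(well, plate_format = 384L) {
  dims <- plate_dims(plate_format)
  w <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-Z][0-9]{1,2}$", w)
  row <- ifelse(ok, match(substr(w, 1, 1), LETTERS), NA_integer_)
  col <- ifelse(ok, suppressWarnings(as.integer(substring(w, 2))), NA_integer_)
  ok <- ok & !is.na(row) & !is.na(col) &
    row >= 1L & row <= dims["rows"] & col >= 1L & col <= dims["cols"]
  out <- rep(NA_character_, length(w))
  out[ok] <- sprintf("%s%02d", substr(w[ok], 1, 1), col[ok])
  out
}

#' All well labels of a plate in row-major order
#' @inheritParams parse_well
#' @export
well_names <- function(plate_format = 384L) {
  dims <- plate_dims(plate_format)
  as.vector(t(outer(LETTERS[seq_len(dims["rows"])],
                    sprintf("%02d", seq_len(dims["cols"])), paste0)))
}

# well table I/O -------------------------------------------------------------

#' Validate a well table against the record invariants
#'
#' Checks the contract every analysis stage relies on: all columns present,
#' readouts non-negative, coordinates valid for the plate format, and sample
#' wells fully annotated with gene and siRNA. Well labels are canonicalised
#' and `role`/`stimulus` checked against the recognised levels.
#'
#' @param wells data.frame with the columns in [WELL_COLUMNS].
#' @param config a `screen_config`.
#' @return the validated (canonicalised) well table.
#' @export
validate_wells <- function(wells, config = screen_config()) {
  missing_cols <- setdiff(WELL_COLUMNS, names(wells))
  if (length(missing_cols)) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  wells <- wells[WELL_COLUMNS]
  for (col in c("screen_id", "plate_id", "well", "sirna_id", "gene_id",
                "role", "stimulus")) {
    wells[[col]] <- as.character(wells[[col]])
  }
  wells$gene_id[is.na(wells$gene_id)] <- ""
  wells$replicate <- as.integer(wells$replicate)
  for (col in c("readout_activity", "readout_viability")) {
    val <- suppressWarnings(as.numeric(wells[[col]]))
    bad <- which(is.na(val) | val < 0)
    if (length(bad)) {
      stop(sprintf("validation error: %s negative or non-numeric at row %d",
                   col, bad[1]), call. = FALSE)
    }
    wells[[col]] <- val
  }
  canon <- parse_well(wells$well, config$plate_format)
  bad <- which(is.na(canon))
  if (length(bad)) {
    stop(sprintf("validation error: malformed well coordinate '%s' at row %d",
                 wells$well[bad[1]], bad[1]), call. = FALSE)
  }
  wells$well <- canon
  bad <- which(!wells$role %in% WELL_ROLES)
  if (length(bad)) {
    stop(sprintf("validation error: unknown role '%s' at row %d",
                 wells$role[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(!wells$stimulus %in% STIMULI)
  if (length(bad)) {
    stop(sprintf("validation error: unknown stimulus '%s' at row %d",
                 wells$stimulus[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(wells$role == "sample" &
                 (wells$gene_id == "" | wells$sirna_id == ""))
  if (length(bad)) {
    stop(sprintf("validation error: sample well lacks gene_id/sirna_id at row %d",
                 bad[1]), call. = FALSE)
  }
  bad <- which(is.na(wells$replicate) | wells$replicate < 1L)
  if (length(bad)) {
    stop(sprintf("validation error: replicate must be a positive integer at row %d",
                 bad[1]), call. = FALSE)
  }
  rownames(wells) <- NULL
  wells
}

#' Read / write a long-format well table
#'
#' One row per well, tab-separated with a header declaring all of
#' [WELL_COLUMNS] (column order is free). Row order is preserved on read.
#'
#' @param path TSV file path.
#' @param config a `screen_config` (sets the plate format for coordinate
#'   checks).
#' @return `read_wells`: the validated well table.
#' @export
read_wells <- function(path, config = screen_config()) {
  if (!file.exists(path)) stop("well table not found: ", path, call. = FALSE)
  wells <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             na.strings = character(0),
                             strip.white = TRUE, fileEncoding = "UTF-8")
  validate_wells(wells, config)
}

#' @rdname read_wells
#' @param wells a validated well table.
#' @export
write_wells <- function(wells, path, config = screen_config()) {
  wells <- validate_wells(wells, config)
  utils::write.table(wells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-plate layout report
#'
#' Counts wells per role on each plate and flags plates missing any required
#' control role. Presence is checked against the configuration's
#' `control_layout` minima; physical positions are not constrained.
#'
#' @param wells well table.
#' @param config a `screen_config`.
#' @return data.frame with one row per plate: role counts, `complete` flag,
#'   and a comma-separated `missing_roles` column. Zero rows for empty input.
#' @export
validate_layout <- function(wells, config = screen_config()) {
  roles <- names(config$control_layout)
  empty <- data.frame(plate_id = character(0))
  for (r in c("sample", roles)) empty[[paste0("n_", r)]] <- integer(0)
  empty$complete <- logical(0)
  empty$missing_roles <- character(0)
  if (!nrow(wells)) return(empty)
  plates <- unique(wells$plate_id)
  out <- lapply(plates, function(p) {
    sub <- wells[wells$plate_id == p, ]
    counts <- vapply(c("sample", roles),
                     function(r) sum(sub$role == r), integer(1))
    required <- config$control_layout
    missing <- roles[counts[roles] < required]
    row <- as.data.frame(as.list(counts))
    names(row) <- paste0("n_", c("sample", roles))
    cbind(data.frame(plate_id = p), row,
          data.frame(complete = length(missing) == 0L,
                     missing_roles = paste(missing, collapse = ",")))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
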