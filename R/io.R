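# Dataset, configuration and results I/O.

DATASET_COLS <- c("ID", "TIME", "AMT", "EVID", "DV", "DVID", "MDV", "BLQ")

#' Write / read a NONMEM-style dataset
#'
#' Comma-separated, period decimal, UTF-8, mandatory header.  Columns `ID`,
#' `TIME` (h since first dose), `AMT` (ng/kg), `EVID` (1 dose, 0
#' observation), `DV` ("." on dose rows), `DVID` (1 concentration, 2 PAR),
#' `MDV`, `BLQ`; an `ARM` column is carried through when present.  Row order
#' is preserved (observations precede dose events at equal times, encoding
#' the pre-dose convention).  `read_dataset` validates the schema and
#' reports offending row numbers.
#'
#' @param x a `pkpd_study` or dataset data frame
#' @param path file path
#' @return `read_dataset`: the validated dataset data frame.
#' @export
write_dataset <- function(x, path) {
  data <- study_data(x)
  out <- data
  out$DV <- ifelse(is.na(out$DV), ".", format(out$DV, digits = 15,
                                              scientific = FALSE,
                                              trim = TRUE))
  out$DVID <- ifelse(is.na(out$DVID), ".", out$DVID)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    stop("read_dataset: no such file: ", path, call. = FALSE)
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"),
                  error = function(e)
                    stop("read_dataset: cannot parse ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!nrow(raw)) stop("read_dataset: empty dataset: ", path, call. = FALSE)
  missing <- setdiff(DATASET_COLS, names(raw))
  if (length(missing))
    stop("read_dataset: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(col) suppressWarnings(as.numeric(ifelse(raw[[col]] == ".",
                                                          NA, raw[[col]])))
  data <- data.frame(ID = num("ID"), TIME = num("TIME"), AMT = num("AMT"),
                     EVID = as.integer(num("EVID")), DV = num("DV"),
                     DVID = as.integer(num("DVID")),
                     MDV = as.integer(num("MDV")),
                     BLQ = as.integer(num("BLQ")))
  if ("ARM" %in% names(raw)) data <- cbind(ARM = as.integer(num("ARM")),
                                           data)[, union("ID", c("ARM",
                                            names(data)))]
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond))
      stop("read_dataset: ", what, " at row(s) ",
           paste(head(which(cond | is.na(cond)), 5), collapse = ", "),
           call. = FALSE)
  }
  bad_row(!data$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  obs <- data$EVID == 0L
  bad_row(obs & !data$DVID %in% c(1L, 2L), "unknown DVID on observation rows")
  bad_row(obs & is.na(data$DV), "missing DV on observation rows")
  bad_row(is.na(data$TIME) | data$TIME < 0, "TIME must be numeric and >= 0")
  bad_row(!data$BLQ %in% c(0L, 1L), "BLQ must be 0 or 1")
  # within a subject, TIME must be non-decreasing
  for (id in unique(data$ID)) {
    tt <- data$TIME[data$ID == id]
    if (any(diff(tt) < 0))
      stop("read_dataset: non-monotone TIME within subject ", id,
           call. = FALSE)
    if (!any(data$ID == id & data$EVID == 1L))
      stop("read_dataset: subject ", id, " has no dose record", call. = FALSE)
  }
  data
}

#' Write a fit-result table
#'
#' Flat CSV mirroring the study's parameter tables: one row per parameter
#' with the typical value, CV% and omega^2 (empty where not estimated),
#' followed by the residual-error rows.
#'
#' @param fit a `pkpd_fit`
#' @param path file path
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pkpd_fit"))
  tab <- data.frame(parameter = names(fit$params),
                    tvP = unname(fit$params),
                    cv_pct = unname(fit$cv_pct[names(fit$params)]),
                    omega2 = unname(fit$omega2[names(fit$params)]))
  res <- fit$residual
  extra <- if (res$type == "mixed")
    data.frame(parameter = c("mult_sd", "res_error"),
               tvP = c(res$mult_sd, res$sigma),
               cv_pct = NA_real_, omega2 = NA_real_)
  else
    data.frame(parameter = "res_error", tvP = res$sigma,
               cv_pct = NA_real_, omega2 = NA_real_)
  write.csv(rbind(tab, extra), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration (YAML)
#'
#' A run configuration holds the parameter sections (`pk`, `pd`,
#' `omega_pk`, `omega_pd`, `residual`), the study design (`design`: list of
#' arms plus `offsets` and `lloq`), and optional `estimation` /
#' `diagnostics` sections.  `read_run_config` parses and validates the YAML
#' file; `config_to_model` and `config_to_design` build the corresponding
#' objects.
#'
#' @param path YAML file path
#' @return `read_run_config`: a named list; `config_to_model`: a
#'   [pop_model]; `config_to_design`: a [study_design].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config: no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pk))
    stop("read_run_config: missing required section 'pk'", call. = FALSE)
  cfg
}

#' @rdname read_run_config
#' @param cfg parsed configuration list
#' @export
config_to_model <- function(cfg) {
  pk <- do.call(pk_params, cfg$pk)
  pd <- if (!is.null(cfg$pd)) do.call(pd_params, cfg$pd)
  res <- if (!is.null(cfg$residual)) do.call(residual_spec, cfg$residual)
         else residual_spec()
  pop_model(pk = pk, pd = pd,
            omega_pk = do.call(omega_spec, as.list(cfg$omega_pk)),
            omega_pd = do.call(omega_spec, as.list(cfg$omega_pd)),
            residual = res)
}

#' @rdname read_run_config
#' @export
config_to_design <- function(cfg) {
  if (is.null(cfg$design)) return(default_beagle_design())
  d <- cfg$design
  arms <- lapply(d$arms, function(a)
    study_arm(n = a$n, dose_mg_kg = a$dose_mg_kg,
              n_doses = if (is.null(a$n_doses)) 1 else a$n_doses,
              sampled_days = if (is.null(a$sampled_days)) 1
                             else unlist(a$sampled_days),
              label = a$label))
  study_design(arms,
               offsets = if (is.null(d$offsets)) beagle_sampling_offsets()
                         else unlist(d$offsets),
               lloq = if (is.null(d$lloq)) 7.8 else d$lloq)
}

#' Write run metadata
#'
#' JSON sidecar identifying a pipeline run: package version, R version,
#' seed, timestamp and the MD5 hash of the configuration file (when given),
#' so any output can be regenerated.
#'
#' @param path output JSON path
#' @param seed integer seed of the run
#' @param config_path optional path of the YAML configuration used
#' @param extra optional named list merged into the metadata
#' @export
write_run_metadata <- function(path, seed, config_path = NULL,
                               extra = list()) {
  meta <- c(list(
    package = "txspkpd",
    version = as.character(utils::packageVersion("txspkpd")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA_character_),
    extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
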