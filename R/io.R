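#' Read observed trials from CSV
#'
#' Reads a behavioural dataset with the header `Cond,Resp,Time` (condition
#' label, chosen alternative, response time in seconds) into the data frame
#' consumed by [log_dens_like()]. Rows with `Resp = 0` and an empty `Time`
#' field (non-terminated simulated trials written by [write_trials()]) are
#' read back with `time = NA`.
#'
#' @param path CSV file path.
#' @return A data frame with columns `cond` (character), `resp` (integer)
#'   and `time` (numeric seconds).
#' @export
read_dataset <- function(path) {
  df <- tryCatch(read.csv(path, colClasses = "character"),
                 error = function(e) stop("cannot read `", path, "`: ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("Cond", "Resp", "Time")
  if (!all(need %in% names(df)))
    stop("dataset CSV must have header columns Cond,Resp,Time (found: ",
         paste(names(df), collapse = ","), ")", call. = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(cond = character(0), resp = integer(0),
                      time = numeric(0)))
  resp <- suppressWarnings(as.integer(df$Resp))
  if (anyNA(resp))
    stop("non-integer Resp at data row ", which(is.na(resp))[1L],
         call. = FALSE)
  time_chr <- trimws(df$Time)
  time <- suppressWarnings(as.numeric(time_chr))
  bad <- which(is.na(time) & nzchar(time_chr))
  if (length(bad))
    stop("non-numeric Time at data row ", bad[1L], call. = FALSE)
  data.frame(cond = df$Cond, resp = resp, time = time)
}

#' Write simulated trials to CSV
#'
#' Writes a [trial_set()] in the `Cond,Resp,Time` format read by
#' [read_dataset()]. Non-terminated trials are written with `Resp = 0` and
#' an empty `Time` field. Times are written with enough digits for a
#' lossless round trip (well below 1e-9).
#'
#' @param trials a [trial_set()].
#' @param path output CSV path.
#' @param cond condition label(s) for the trials (recycled).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, cond = "1") {
  time_chr <- ifelse(is.na(trials$rt), "",
                     sprintf("%.15g", trials$rt))
  df <- data.frame(Cond = rep_len(as.character(cond), nrow(trials)),
                   Resp = trials$resp, Time = time_chr)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a named-parameter configuration file
#'
#' Parameter sets are plain named keys (e.g. `vc, ve, A, b, t0` for the
#' LBA) in JSON or YAML, chosen by file extension. A top-level key
#' `lut.granularity` (or nested `lut: granularity:`) overrides the default
#' look-up-table granularity. A file whose top-level values are
#' themselves mappings is a per-condition parameter map for
#' [log_dens_like()].
#'
#' @param path `.json`, `.yaml` or `.yml` file path.
#' @return A named list.
#' @export
read_params_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("config must be .json, .yaml or .yml", call. = FALSE))
  if (!is.list(cfg)) stop("config must be a mapping of named keys",
                          call. = FALSE)
  cfg
}
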