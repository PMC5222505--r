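# Delimited-text interchange. A stimulus-response pair is one table with
# header columns s0..s{D-1}, r0..r{R-1}; every file gets a JSON sidecar
# (<path>.json) carrying the metadata needed to re-derive it: dt, sigma,
# response mode, shapes, seeds/parameters where applicable, and for
# matrices the role/tau/layout/normalization/demeaned descriptors.

sep_for <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

# render doubles with 17 significant digits so written values parse back
# bit-exact (default delimited-text writers stop at 15 and lose ulps)
fmt_exact <- function(tab) {
  for (j in names(tab)) {
    if (is.double(tab[[j]]))
      data.table::set(tab, j = j, value = sprintf("%.17g", tab[[j]]))
  }
  tab
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else list()
}

#' Write a stimulus-response pair to delimited text
#'
#' One row per time bin; stimulus columns named `s0..s{D-1}`, response
#' columns `r0..r{R-1}`. Extension selects the delimiter (`.tsv` for
#' tab, comma otherwise). A JSON sidecar `<path>.json` stores dt, sigma,
#' the response mode and any extra parameters supplied.
#'
#' @param stimulus A \code{\link{stimulus_ensemble}}.
#' @param responses A \code{\link{response_set}} (or NULL to write the
#'   stimulus alone).
#' @param path Output file path (.csv or .tsv).
#' @param extra Named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_stimulus_response <- function(stimulus, responses, path, extra = list()) {
  if (!inherits(stimulus, "stimulus_ensemble"))
    stop_validation("stimulus must be a stimulus_ensemble")
  S <- stimulus$values
  tab <- data.table::as.data.table(S)
  data.table::setnames(tab, paste0("s", seq_len(ncol(S)) - 1L))
  meta <- list(T = nrow(S), D = ncol(S), dt = stimulus$dt, sigma = stimulus$sigma)
  if (!is.null(responses)) {
    if (!inherits(responses, "response_set"))
      stop_validation("responses must be a response_set")
    if (nrow(responses$values) != nrow(S))
      stop_dimension("stimulus and response lengths differ")
    Rv <- responses$values
    rtab <- data.table::as.data.table(Rv)
    data.table::setnames(rtab, paste0("r", seq_len(ncol(Rv)) - 1L))
    tab <- cbind(tab, rtab)
    meta$R <- ncol(Rv)
    meta$mode <- responses$mode
  }
  meta <- c(meta, extra)
  data.table::fwrite(fmt_exact(tab), path, sep = sep_for(path))
  write_sidecar(path, meta)
  invisible(path)
}

#' Read a stimulus-response pair from delimited text
#'
#' Expects the column convention of
#' \code{\link{write_stimulus_response}}; `dt`, `sigma` and the response
#' mode are taken from the JSON sidecar when present, else from the
#' arguments.
#'
#' @param path Input .csv/.tsv file.
#' @param dt,sigma Fallbacks when no sidecar is present.
#' @param mode Fallback response mode.
#' @return List with `stimulus` (\code{\link{stimulus_ensemble}}) and
#'   `responses` (\code{\link{response_set}} or NULL).
#' @export
read_stimulus_response <- function(path, dt = 1, sigma = 1,
                                   mode = c("continuous", "spike-counts")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  tab <- data.table::fread(path, sep = sep_for(path), header = TRUE)
  nms <- names(tab)
  scols <- grep("^s[0-9]+$", nms, value = TRUE)
  rcols <- grep("^r[0-9]+$", nms, value = TRUE)
  if (length(scols) == 0L)
    stop_validation("no stimulus columns found (expected header s0, s1, ...)")
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  rcols <- rcols[order(as.integer(sub("^r", "", rcols)))]
  meta <- read_sidecar(path)
  if (!is.null(meta$dt)) dt <- meta$dt
  if (!is.null(meta$sigma)) sigma <- meta$sigma
  if (!is.null(meta$mode)) mode <- meta$mode
  stim <- stimulus_ensemble(as.matrix(tab[, scols, with = FALSE]),
                            dt = dt, sigma = sigma)
  resp <- if (length(rcols) > 0L)
    response_set(as.matrix(tab[, rcols, with = FALSE]), mode = mode) else NULL
  list(stimulus = stim, responses = resp)
}

#' Write a kernel / covariance / STC matrix to delimited text
#'
#' The full (D*L) x (D*L) matrix, no header, plus a JSON sidecar with
#' the descriptors `role`, `tau`, `D`, `layout`, `normalization`,
#' `demeaned` (and dt/sigma when recorded).
#'
#' @param cov A `block_cov`.
#' @param path Output .csv/.tsv file.
#' @param extra Named list of extra sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_block_cov <- function(cov, path, extra = list()) {
  if (!inherits(cov, "block_cov")) stop_validation("cov must be a block_cov")
  data.table::fwrite(fmt_exact(data.table::as.data.table(cov$matrix)), path,
                     sep = sep_for(path), col.names = FALSE)
  meta <- c(list(role = cov$role, tau = cov$tau, D = cov$D,
                 layout = cov$layout, normalization = cov$normalization,
                 demeaned = cov$demeaned, dt = cov$dt, sigma = cov$sigma),
            extra)
  write_sidecar(path, meta)
  invisible(path)
}

#' Read a kernel / covariance / STC matrix written by
#' \code{\link{write_block_cov}}
#'
#' @param path Input .csv/.tsv file (its `.json` sidecar must exist).
#' @return A `block_cov`.
#' @export
read_block_cov <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  meta <- read_sidecar(path)
  if (is.null(meta$role))
    stop_validation("matrix sidecar missing or incomplete (need role/tau/D)")
  M <- as.matrix(data.table::fread(path, sep = sep_for(path), header = FALSE))
  dimnames(M) <- NULL
  new_block_cov(M, role = meta$role, tau = meta$tau, D = meta$D,
                normalization = meta$normalization,
                demeaned = isTRUE(meta$demeaned),
                dt = if (is.null(meta$dt)) NA_real_ else meta$dt,
                sigma = if (is.null(meta$sigma)) NA_real_ else meta$sigma)
}
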