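#' Write an edited scan as a bundle of rda-dialect block files
#'
#' One text file per block: a `key: value` header delimited by marker lines,
#' followed by whitespace-separated real/imaginary pairs (one point per line,
#' 17 significant digits, so doubles round-trip exactly). A `manifest.json`
#' lists the block files and scan metadata.
#'
#' @param scan an [edited_scan()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_rda_bundle <- function(scan, dir) {
  stopifnot(inherits(scan, "edited_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (blk in c(scan$off, scan$on)) {
    fn <- sprintf("block_%s_%03d.rda", blk$edit_state, blk$block_index)
    hdr <- c(
      ">>> Begin of header <<<",
      sprintf("VectorSize: %d", length(blk$values)),
      sprintf("TransmitFrequency: %.17g", blk$f0),
      sprintf("DwellTime: %.17g", blk$dwell * 1e6),
      sprintf("EditState: %s", blk$edit_state),
      sprintf("ScanId: %s", blk$scan_id),
      sprintf("BlockIndex: %d", blk$block_index),
      ">>> End of header <<<")
    dat <- sprintf("%.17g %.17g", Re(blk$values), Im(blk$values))
    writeLines(c(hdr, dat), file.path(dir, fn))
    files <- c(files, fn)
  }
  manifest <- list(scan_id = scan$off[[1]]$scan_id,
                   n_on = length(scan$on), n_off = length(scan$off),
                   files = files, meta = scan$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an rda-dialect scan bundle
#'
#' Parses every block file listed in the bundle manifest (or all `block_*.rda`
#' files if no manifest is present), validating the header and the point
#' count, and reassembles the [edited_scan()]. A write/read cycle reproduces
#' the block values exactly.
#'
#' @param dir bundle directory written by [write_rda_bundle()].
#' @return an [edited_scan()].
#' @export
read_rda_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir)
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    files <- manifest$files
    meta <- manifest$meta
  } else {
    files <- sort(basename(Sys.glob(file.path(dir, "block_*.rda"))))
    meta <- list()
  }
  if (length(files) == 0) stop("no block files found in ", dir)
  blocks <- lapply(files, function(fn) read_rda_block(file.path(dir, fn)))
  states <- vapply(blocks, function(b) b$edit_state, "")
  edited_scan(blocks[states == "On"], blocks[states == "Off"],
              meta = as.list(meta))
}

read_rda_block <- function(path) {
  if (!file.exists(path)) stop("block file missing: ", path)
  lines <- readLines(path)
  if (length(lines) < 3 || !grepl("^>>> Begin of header", lines[1])) {
    stop("malformed header in ", basename(path), ": missing begin marker")
  }
  end <- grep("^>>> End of header", lines)
  if (length(end) != 1) {
    stop("malformed header in ", basename(path), ": missing end marker")
  }
  hdr <- lines[2:(end - 1)]
  kv <- regmatches(hdr, regexec("^([A-Za-z]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  h <- stats::setNames(as.list(vals), keys)
  for (req in c("VectorSize", "TransmitFrequency", "DwellTime",
                "EditState", "ScanId", "BlockIndex")) {
    if (is.null(h[[req]])) {
      stop("malformed header in ", basename(path), ": missing field ", req)
    }
  }
  if (!h$EditState %in% c("On", "Off")) {
    stop("invalid EditState \"", h$EditState, "\" in ", basename(path))
  }
  n <- as.integer(h$VectorSize)
  dat <- lines[(end + 1):length(lines)]
  dat <- dat[nzchar(trimws(dat))]
  if (length(dat) != n) {
    stop("wrong point count in ", basename(path), ": VectorSize ", n,
         " but ", length(dat), " data lines")
  }
  num <- utils::read.table(text = dat, col.names = c("re", "im"))
  block_spectrum(complex(real = num$re, imaginary = num$im),
                 f0 = as.numeric(h$TransmitFrequency),
                 dwell = as.numeric(h$DwellTime) * 1e-6,
                 edit_state = h$EditState,
                 scan_id = h$ScanId,
                 block_index = as.integer(h$BlockIndex),
                 preprocessed = n == 4096L)
}
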