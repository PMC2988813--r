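#' Read a quantified spot table from a scanner export
#'
#' Reads one array's spot-level feature table, either as a plain
#' tab-delimited file with a single header line (`format = "plain-tsv"`)
#' or as a GenePix-style export whose preamble of `"key=value"` header
#' lines is skipped by locating the column-header line
#' (`format = "gpr-like"`). Exact column names differ between scanner
#' software versions, so the mapping from logical fields to column
#' names is supplied via `columns`.
#'
#' Rows whose mapped numeric fields cannot be parsed are skipped and
#' recorded in the parse report (`attr(x, "parse_report")`) rather than
#' silently dropped; missing values written as `NA` or empty are kept
#' as missing only in optional fields, while an unparseable required
#' signal skips the row.
#'
#' @param path Path to the file.
#' @param format `"plain-tsv"` or `"gpr-like"`.
#' @param columns Named list mapping logical fields to column names:
#'   `id` (feature identifier), `flag` (quality flag), `channels`
#'   (named character vector, channel name -> net-signal column), and
#'   optionally `sob` (channel -> signal-over-background column) and
#'   `regcorr` (regression-correlation column).
#' @param spot_index_col Optional column holding the duplicate-spot
#'   number; when absent, spots are numbered in file order within each
#'   feature.
#' @param assume_flag If the flag column is absent, use this constant
#'   flag for every spot (e.g. `0`); if `NULL` (default) a missing flag
#'   column is an error.
#' @param array_id Identifier for the array; defaults to the file name.
#'
#' @return An object of class `"array_scan"`: a list with elements
#'   `array_id`, `features` (a data frame with columns `feature_id`,
#'   `spot_index`, `flag`, one `net.<channel>` column per channel, and
#'   any optional QC columns) and `channel_names`. The attribute
#'   `"parse_report"` records row counts read, kept and skipped.
#' @export
read_array_table <- function(path,
                             format = c("plain-tsv", "gpr-like"),
                             columns = list(id = "feature_id",
                                            flag = "flag",
                                            channels = c(Cy3 = "net_Cy3",
                                                         Cy5 = "net_Cy5")),
                             spot_index_col = NULL,
                             assume_flag = NULL,
                             array_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(lines)))
    stop("empty input file: ", path)

  if (format == "gpr-like") {
    # locate the column-header line: first tab-split line containing the
    # feature-ID column name (GPR preambles never do)
    hdr <- which(vapply(strsplit(lines, "\t", fixed = TRUE),
                        function(f) columns$id %in% gsub("^\"|\"$", "", f),
                        logical(1)))[1]
    if (is.na(hdr))
      stop("could not locate a header line naming column '", columns$id,
           "' in GPR-like file ", path)
    lines <- lines[hdr:length(lines)]
  }

  tab <- read.delim(text = lines, header = TRUE, sep = "\t",
                    quote = "\"", check.names = FALSE,
                    colClasses = "character",
                    blank.lines.skip = TRUE,
                    stringsAsFactors = FALSE)

  need <- c(columns$id, unname(columns$channels))
  flag_col <- columns$flag
  if (!is.null(flag_col) && !(flag_col %in% names(tab))) {
    if (is.null(assume_flag))
      stop("missing mandatory column '", flag_col, "' in ", path,
           " (set assume_flag to supply a default)")
    flag_col <- NULL
  }
  missing_cols <- setdiff(c(need, flag_col), names(tab))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))

  n_read <- nrow(tab)
  num <- function(x) suppressWarnings(as.numeric(x))

  sig <- vapply(unname(columns$channels), function(cn) num(tab[[cn]]),
                numeric(n_read))
  sig <- matrix(sig, nrow = n_read)
  flag <- if (is.null(flag_col)) rep(as.numeric(assume_flag), n_read)
          else num(tab[[flag_col]])
  bad <- rowSums(!is.finite(sig)) > 0 | !is.finite(flag)
  skipped <- which(bad)

  keep <- tab[!bad, , drop = FALSE]
  feat <- data.frame(feature_id = keep[[columns$id]],
                     stringsAsFactors = FALSE)
  feat$spot_index <- if (!is.null(spot_index_col) &&
                         spot_index_col %in% names(keep))
    as.integer(num(keep[[spot_index_col]]))
  else ave(seq_len(nrow(keep)), feat$feature_id, FUN = seq_along)
  feat$flag <- flag[!bad]
  for (ch in names(columns$channels))
    feat[[paste0("net.", ch)]] <- num(keep[[columns$channels[[ch]]]])
  if (!is.null(columns$sob))
    for (ch in names(columns$sob))
      feat[[paste0("sob.", ch)]] <- num(keep[[columns$sob[[ch]]]])
  if (!is.null(columns$regcorr))
    feat$regression_correlation <- num(keep[[columns$regcorr]])

  scan <- structure(list(array_id = array_id, features = feat,
                         channel_names = names(columns$channels)),
                    class = "array_scan")
  attr(scan, "parse_report") <- list(n_read = n_read,
                                     n_kept = nrow(feat),
                                     n_skipped = length(skipped),
                                     skipped_rows = skipped)
  scan
}

#' Remove control features and flagged spots
#'
#' Drops spot rows whose feature ID matches any control pattern
#' (shell-style globs, e.g. `"GST*"`) and rows whose quality flag is
#' below `min_flag`. The default `min_flag = 0` retains spots flagged
#' zero or positive and drops negatively flagged (bad) spots. The
#' operation is idempotent; removal counts are attached as the
#' `"filter_report"` attribute.
#'
#' @param x An `"array_scan"` or its spot data frame.
#' @param drop_controls Character vector of glob patterns for control
#'   feature IDs to remove.
#' @param min_flag Minimum flag retained (spots with `flag < min_flag`
#'   are removed).
#' @return Same type as `x`, filtered.
#' @export
filter_features <- function(x, drop_controls = character(), min_flag = 0) {
  feat <- if (inherits(x, "array_scan")) x$features else x
  is_control <- rep(FALSE, nrow(feat))
  for (pat in drop_controls)
    is_control <- is_control | grepl(glob2rx(pat), feat$feature_id)
  bad_flag <- !is.na(feat$flag) & feat$flag < min_flag
  out <- feat[!is_control & !bad_flag, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(n_in = nrow(feat),
                 n_controls_removed = sum(is_control),
                 n_flag_removed = sum(bad_flag & !is_control),
                 n_out = nrow(out),
                 min_flag = min_flag)
  if (inherits(x, "array_scan")) {
    x$features <- out
    attr(x, "filter_report") <- report
    x
  } else {
    attr(out, "filter_report") <- report
    out
  }
}

#' Average duplicate spots within one array
#'
#' Computes, per feature and channel, the arithmetic mean of net signal
#' over retained duplicate spots, after excluding negatively flagged
#' spots. Features whose spots were all excluded are absent from the
#' result and listed in the `"absent_features"` attribute: absence is
#' data, not an error.
#'
#' @param scan An `"array_scan"`.
#' @return A numeric matrix, features x channels, with feature IDs as
#'   row names and channel names as column names.
#' @export
average_duplicate_spots <- function(scan) {
  stopifnot(inherits(scan, "array_scan"))
  feat <- scan$features
  ok <- is.na(feat$flag) | feat$flag >= 0
  kept <- feat[ok, , drop = FALSE]
  ids <- unique(feat$feature_id)
  chans <- scan$channel_names
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(chans),
                dimnames = list(ids, chans))
  if (nrow(kept) > 0) {
    for (ch in chans) {
      v <- tapply(kept[[paste0("net.", ch)]], kept$feature_id,
                  function(x) mean(x, na.rm = TRUE))
      out[names(v), ch] <- unname(v)
    }
    out[is.nan(out)] <- NA_real_
  }
  absent <- ids[!ids %in% kept$feature_id]
  out <- out[!(rownames(out) %in% absent), , drop = FALSE]
  attr(out, "absent_features") <- absent
  out
}

#' Assemble a feature table from replicate array scans
#'
#' Stacks per-array duplicate-averaged signals for one channel into a
#' features x arrays matrix (a "feature table"), the input to the
#' rank- and Z-score-based binder selections. Features absent from an
#' array are missing in that column.
#'
#' @param scans List of `"array_scan"` objects.
#' @param channel Channel name to extract.
#' @return Numeric matrix, features x arrays, with feature IDs as row
#'   names and array IDs as column names.
#' @export
feature_table <- function(scans, channel) {
  stopifnot(length(scans) >= 1)
  avgs <- lapply(scans, average_duplicate_spots)
  ids <- unique(unlist(lapply(avgs, rownames)))
  arr <- vapply(scans, function(s) s$array_id, character(1))
  if (anyDuplicated(arr)) stop("array IDs must be unique within a dataset")
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(arr),
                dimnames = list(ids, arr))
  for (j in seq_along(avgs)) {
    a <- avgs[[j]]
    if (!channel %in% colnames(a))
      stop("channel '", channel, "' not present in array ", arr[j])
    out[rownames(a), j] <- a[, channel]
  }
  out
}

#' Write and re-read a feature table as TSV
#'
#' Values are written with 17 significant digits so that finite doubles
#' survive a write/read round trip bit-exactly.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the matrix.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  fmt <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  fmt[is.na(x)] <- "NA"
  df <- data.frame(feature_id = rownames(x), fmt, stringsAsFactors = FALSE)
  names(df) <- c("feature_id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read a gene-to-term annotation table
#'
#' Reads a tab-delimited annotation file with columns `gene_id`,
#' `namespace`, `term_id`, `term_name` and returns the rows for one
#' namespace as a data frame suitable for [annotation_map()].
#'
#' @param path Path to the TSV file.
#' @param namespace Optional namespace (`"process"`, `"function"`,
#'   `"compartment"`, `"pfam"`) to restrict to.
#' @return Data frame with the four annotation columns.
#' @export
read_annotation_table <- function(path, namespace = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "namespace", "term_id", "term_name")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("annotation file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(namespace)) df <- df[df$namespace == namespace, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @importFrom utils glob2rx
#' @importFrom stats ave
NULL
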