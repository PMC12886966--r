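# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical variant key: contig:pos(1-based):ref:alt
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
ndd_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "nddtrio_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# Half-open 0-based interval sanity check
check_interval <- function(start, end, what = "interval") {
  if (any(start < 0)) ndd_stop(sprintf("%s has negative start", what), "coord_error")
  if (any(end <= start)) ndd_stop(sprintf("%s has end <= start", what), "coord_error")
  invisible(TRUE)
}

# Convert half-open 0-based [start, end) to IRanges (1-based closed) and back
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)
from_iranges_start <- function(ir) IRanges::start(ir) - 1L
from_iranges_end <- function(ir) IRanges::end(ir)

# Row-binding of data frames that tolerates an empty list
rbind_df <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

empty_df <- function(cols) {
  # cols: named list of prototype vectors
  as.data.frame(lapply(cols, function(x) x[0]), stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE, comment.char = "",
                    quote = "", ...)
}
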