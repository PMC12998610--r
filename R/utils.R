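# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Field separator for linkage keys. Gene/cell-type names must not contain it.
.SEP <- "|"

.join_key <- function(...) paste(..., sep = .SEP)

.split_key <- function(x) strsplit(x, .SEP, fixed = TRUE)

# Deterministic 31-bit sub-seed derived from integer components. Keeps every
# derived seed below 2^31 so it is a valid R integer seed.
.mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (p %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

.stop_cond <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "linksig_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

.stop_input <- function(msg) .stop_cond("linksig_input_error", msg)
.stop_parse <- function(msg) .stop_cond("linksig_parse_error", msg)
.stop_usage <- function(msg) .stop_cond("linksig_usage_error", msg)

# Delimiter by extension: .csv -> comma, anything else tab.
.delim_for <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

.read_table <- function(path, header = TRUE) {
  if (!file.exists(path)) .stop_input(sprintf("file not found: %s", path))
  utils::read.table(path,
    header = header, sep = .delim_for(path), quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE, comment.char = ""
  )
}

# Row z-score with population SD (divide by n). Constant rows map to zero so
# they can never pass a strictly-positive mean-scaled-expression gate.
.zscore_rows <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  m <- rowMeans(x)
  v <- rowMeans(x * x) - m * m
  v[v < 0] <- 0
  s <- sqrt(v)
  out <- (x - m) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
}
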