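# Internal helpers: typed errors, hashing, TSV with provenance headers.

tail_te_error <- function(msg, class, call = sys.call(-1)) {
  structure(
    class = c(class, "tailTE_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

abort_tailTE <- function(msg, class = "tailTE_error_generic") {
  stop(tail_te_error(msg, class))
}

assert_that <- function(ok, msg, class = "tailTE_error_invalid") {
  if (!isTRUE(ok)) abort_tailTE(msg, class)
  invisible(TRUE)
}

# Polynomial rolling hash over the deparsed object; stable across sessions.
# Not cryptographic -- used only to fingerprint configurations in manifests.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  p <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% p
  sprintf("%010d", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format doubles so that write -> read round-trips exactly.
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

#' Write a TSV table with a provenance header block
#'
#' All pipeline writers emit a block of `# key<TAB>value` lines ahead of the
#' column header; all readers skip it. No timestamps are written, so repeated
#' runs on identical inputs are byte-identical.
#'
#' @param df data frame (list columns are dropped with a warning).
#' @param path output path.
#' @param provenance named character vector recorded in the header block.
#' @return `path`, invisibly.
#' @keywords internal
write_tsv_prov <- function(df, path, provenance = character()) {
  is_list_col <- vapply(df, is.list, logical(1))
  if (any(is_list_col)) df <- df[!is_list_col]
  out <- df
  for (j in seq_along(out)) out[[j]] <- format_full(out[[j]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(provenance)) {
    writeLines(paste0("# ", names(provenance), "\t", provenance), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @keywords internal
read_tsv_prov <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "tailTE_error_io")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  df
}

read_provenance <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  if (!length(hdr)) return(character())
  parts <- strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = "\t"),
                         character(1)),
                  vapply(parts, `[[`, character(1), 1))
}

# Midpoint-convention median (stats::median already does this for even n;
# kept as a named wrapper so the convention is explicit at call sites).
median_midpoint <- function(x) stats::median(x)
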