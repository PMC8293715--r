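#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix and no call noise
abort_ <- function(...) stop(..., call. = FALSE)

# numeric scalar check used by config validators
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# significance stars following the usual <.05 / <.01 / <.001 convention
p_stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# sample SD = 0 guard
has_spread <- function(x) {
  x <- x[is.finite(x)]
  length(x) >= 2L && stats::sd(x) > 0
}

# canonical label form for case/whitespace-insensitive matching
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# write a data.frame deterministically (fixed field order, no row names)
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
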