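#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed fan-out from one global seed. Keeps every
# derived seed inside the 32-bit signed-integer range R requires.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stage_num <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 2654435L + stage_num * 40503L) %% 2147483647L)
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_named <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# dense row-wise helpers on a (cells x genes) Matrix without densifying all
row_totals <- function(m) as.numeric(Matrix::rowSums(m))

# case-insensitive, whitespace-stripped gene symbol normalization used for
# cross-omics matching
normalize_symbols <- function(x) toupper(trimws(as.character(x)))
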