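# internal helpers shared across modules

.SPACE_IDS <- c("W_CT", "C_CT", "RCW_GA", "RCC_GA")
.FORMS <- c("+FW", "+RC", "-FW", "-RC")
.STRAND_CODE <- c("+FW" = "++", "+RC" = "+-", "-FW" = "-+", "-RC" = "--")
.RC_FORMS <- c("+RC", "-RC")

.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# three-letter collapses; idempotent by construction
.ct <- function(x) chartr("C", "T", x)
.ga <- function(x) chartr("G", "A", x)

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.check_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  invisible(x)
}
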