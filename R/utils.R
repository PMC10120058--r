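## internal helpers

# site-class codes shared with the C++ engine (0-based)
.CLASS_LEVELS <- c("tsr_target", "exon_neutral", "exon_deleterious",
                   "noncoding_neutral")

.classLabel <- function(code) .CLASS_LEVELS[code + 1L]

.classCode <- function(label) {
  m <- match(label, .CLASS_LEVELS)
  if (anyNA(m)) stop("unknown site class: ",
                     paste(label[is.na(m)], collapse = ", "))
  m - 1L
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.assertCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != round(x))
    stop("'", name, "' must be a single integer >= ", min)
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single probability in [0, 1]")
  as.numeric(x)
}
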