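# internal helpers shared across modules

#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; assembly reports conventionally
#' round half up (e.g. depth printed as 70.55x), so reported numbers go through
#' this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# evaluate `expr` under a fixed RNG state, restoring the caller's state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# random i.i.d. DNA string with a target GC fraction
randomDNA <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# point-mutate a sequence: each base substituted with prob `rate`
mutateDNA <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    repl <- vapply(ch[hit],
                   function(b) sample(setdiff(alt, b), 1L),
                   character(1))
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# lower median: for even n, the smaller of the two central order statistics
lowerMedian <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

# coerce ScaffoldSet / DNAStringSet / named character to DNAStringSet
asDNAStringSet <- function(x) {
  if (is(x, "ScaffoldSet")) return(scaffoldSeqs(x))
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    ss <- Biostrings::DNAStringSet(x)
    if (is.null(names(ss))) names(ss) <- paste0("seq", seq_along(ss))
    return(ss)
  }
  stop("cannot coerce object of class ", class(x)[1], " to DNAStringSet")
}
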