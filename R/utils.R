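#' @useDynLib milrscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is show
#' @importFrom stats phyper rnorm runif t.test setNames
#' @importFrom utils adist read.delim write.table head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never disturbs user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

#' Reverse complement of a DNA/RNA string
#'
#' Complements A/C/G/T/U and reverses. T and U are each complemented to A;
#' A is complemented to T (DNA convention, matching the package-wide policy
#' of storing sequences as DNA).
#'
#' @param x character vector of sequences (uppercase A/C/G/T/U).
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("U", "T", s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# integer encoding used by the C++ engine: A=1 C=2 G=3 U/T=4
encodeSeq <- function(s) {
  v <- strsplit(chartr("T", "U", toupper(s)), "")[[1]]
  code <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  out <- unname(code[v])
  if (anyNA(out))
    stop("invalid character(s) in sequence: ",
         paste(unique(v[is.na(out)]), collapse = ", "))
  out
}

pairOK <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG",
                      "AT", "TA", "GT", "TG")
}

# "contig:start-end" formatting used in reports
formatLocus <- function(contig, start, end) sprintf("%s:%d-%d", contig, start, end)

parseLocus <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed locus string: ", x[bad][1])
  data.frame(contig = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)),
             end = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}
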