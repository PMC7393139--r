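#' @importFrom stats rnorm rbinom rnbinom rpois rbeta runif rlnorm median
#'   quantile setNames complete.cases
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily fixed RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state so simulations are reproducible without
#' clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Beta shape parameters for a target median and concentration a+b.
# Uses the standard median approximation (a - 1/3)/(a + b - 2/3), accurate
# to ~0.003 for the medians used here.
beta_shapes_for_median <- function(m, concentration) {
  m <- unname(m); concentration <- unname(concentration)
  a <- m * (concentration - 2 / 3) + 1 / 3
  b <- concentration - a
  if (a <= 0 || b <= 0) stop("median/concentration combination infeasible")
  c(a = a, b = b)
}

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# random in-frame coding sequence: ATG + (n_codons - 2) non-stop codons + stop
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  codons <- names(Biostrings::GENETIC_CODE)
  nonstop <- setdiff(codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(nonstop, n_codons - 2, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

# draw n integers uniformly from an inclusive range; safe when the range is
# degenerate (sample() would otherwise treat a scalar as 1:x)
rint <- function(range, n = 1) {
  if (range[1] == range[2]) return(rep(as.integer(range[1]), n))
  sample(seq(range[1], range[2]), n, replace = TRUE)
}
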