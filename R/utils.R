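#' @keywords internal
"_PACKAGE"

# altitude class of each subpopulation; the two-population contrast everywhere
# downstream is highland (Tibet + Qinghai) vs lowland (Xinjiang + InnerMongolia)
SUBPOP_CLASS <- c(
  Tibet = "highland", Qinghai = "highland",
  Xinjiang = "lowland", InnerMongolia = "lowland"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("altisweep_input_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("altisweep_data_error", "error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package operations do not
#' disturb the caller's random-number stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# standard genetic code, indexed by codon string
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    lut <- c(
      TTT = "F", TTC = "F", TTA = "L", TTG = "L",
      CTT = "L", CTC = "L", CTA = "L", CTG = "L",
      ATT = "I", ATC = "I", ATA = "I", ATG = "M",
      GTT = "V", GTC = "V", GTA = "V", GTG = "V",
      TCT = "S", TCC = "S", TCA = "S", TCG = "S",
      CCT = "P", CCC = "P", CCA = "P", CCG = "P",
      ACT = "T", ACC = "T", ACA = "T", ACG = "T",
      GCT = "A", GCC = "A", GCA = "A", GCG = "A",
      TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
      CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
      AAT = "N", AAC = "N", AAA = "K", AAG = "K",
      GAT = "D", GAC = "D", GAA = "E", GAG = "E",
      TGT = "C", TGC = "C", TGA = "*", TGG = "W",
      CGT = "R", CGC = "R", CGA = "R", CGG = "R",
      AGT = "S", AGC = "S", AGA = "R", AGG = "R",
      GGT = "G", GGC = "G", GGA = "G", GGG = "G"
    )
    unname(lut[cd])
  }, character(1))
  names(aa) <- codons
  aa
})

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[toupper(codon)]
  ifelse(is.na(aa), "X", aa)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

#' Write sequences as FASTA (60-column wrap)
#' @param sequences named character vector of sequences
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, n)), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file
#' @return named character vector
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
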