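#' Construct an aligned mitochondrial sequence set
#'
#' The central sequence container: one aligned locus (equal-length sequences,
#' alphabet `A,C,G,T,N,-`) with individual, population and species annotation
#' per record.
#'
#' @param individual,population,species Character vectors, one entry per
#'   record; individual ids must be unique.
#' @param sequence Character vector of aligned sequences (equal length,
#'   uppercase).
#' @return A data frame of class `mtdna_alignment` with an `aln_length`
#'   attribute.
#' @export
mtdna_alignment <- function(individual, population, species, sequence) {
  individual <- as.character(individual)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(individual))
    stop("duplicate individual id(s): ",
         paste(unique(individual[duplicated(individual)]), collapse = ", "))
  lens <- nchar(sequence)
  if (length(unique(lens)) > 1) {
    bad <- individual[lens != lens[1]][1]
    stop("sequence length mismatch: record '", bad, "' has length ",
         nchar(sequence[individual == bad][1]), ", expected ", lens[1])
  }
  if (any(grepl("[^ACGTN-]", sequence)))
    stop("sequences contain characters outside {A,C,G,T,N,-}")
  out <- data.frame(individual = individual,
                    population = as.character(population),
                    species = as.character(species),
                    sequence = sequence,
                    stringsAsFactors = FALSE)
  attr(out, "aln_length") <- lens[1]
  class(out) <- c("mtdna_alignment", "data.frame")
  out
}

#' Read an aligned FASTA plus its population table
#'
#' FASTA headers may be bare individual ids or `indID|popID|species`; in
#' either case the part before the first `|` is the individual id, which is
#' joined against the population CSV (`individual,population,species,lon,lat`).
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param populations_path Path to the population CSV.
#' @return A list with `alignment` (an [mtdna_alignment()]) and `populations`
#'   (a data frame `population,species,lon,lat`, one row per population).
#' @export
read_alignment <- function(fasta_path, populations_path) {
  dna <- ape::read.FASTA(fasta_path)
  ids <- vapply(strsplit(names(dna), "|", fixed = TRUE), `[`, "", 1)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  meta <- utils::read.csv(populations_path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "species", "lon", "lat")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("population table lacks column(s): ", paste(miss, collapse = ", "))
  m <- match(ids, meta$individual)
  if (anyNA(m))
    stop("individual(s) missing from population table: ",
         paste(ids[is.na(m)], collapse = ", "))
  aln <- mtdna_alignment(ids, meta$population[m], meta$species[m], seqs)
  pops <- unique(meta[, c("population", "species", "lon", "lat")])
  rownames(pops) <- NULL
  list(alignment = aln, populations = pops)
}

#' Write an alignment as FASTA with `ind|pop|species` headers
#'
#' @param aln An [mtdna_alignment()].
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  hdr <- paste0(">", aln$individual, "|", aln$population, "|", aln$species)
  writeLines(as.vector(rbind(hdr, aln$sequence)), path)
  invisible(path)
}

#' Collapse identical sequences into haplotypes
#'
#' Exact string identity (with `N` and `-` compared literally) defines a
#' haplotype; members partition the individuals.
#'
#' @param aln An [mtdna_alignment()].
#' @return An object of class `haplotype_set`: `haplotypes` (data frame
#'   `haplotype,sequence,n_members`), `members` (data frame
#'   `individual,population,species,haplotype`) and an `assignment` slot
#'   (haplotype to mtDNA lineage), `NULL` until [assign_lineages()] runs.
#' @export
collapse_haplotypes <- function(aln) {
  if (nrow(aln) == 0) stop("empty alignment")
  first <- !duplicated(aln$sequence)
  uniq <- aln$sequence[first]
  hap_id <- sprintf("H%03d", seq_along(uniq))
  map <- hap_id[match(aln$sequence, uniq)]
  structure(
    list(haplotypes = data.frame(haplotype = hap_id, sequence = uniq,
                                 n_members = as.vector(table(map)[hap_id]),
                                 stringsAsFactors = FALSE),
         members = data.frame(individual = aln$individual,
                              population = aln$population,
                              species = aln$species,
                              haplotype = map, stringsAsFactors = FALSE),
         assignment = NULL),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes over %d individuals\n",
              nrow(x$haplotypes), nrow(x$members)))
  if (!is.null(x$assignment))
    cat("  lineages:", paste(unique(x$assignment$lineage), collapse = ", "), "\n")
  invisible(x)
}

# Character matrix (records x sites) from sequences; used by all pairwise
# mismatch computations.
seq_char_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}

#' Count pairwise differences between two aligned sequences
#'
#' Sites where either sequence holds `N` or `-` are excluded (pairwise
#' deletion); the proportion is mismatches over compared sites.
#'
#' @param a,b Equal-length sequence strings.
#' @return A list with `mismatches`, `compared` and `proportion`.
#' @export
pairwise_differences <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  compared <- sum(ok)
  if (compared == 0)
    stop("no resolved sites shared by the two sequences; proportion undefined")
  mm <- sum(x[ok] != y[ok])
  list(mismatches = mm, compared = compared, proportion = mm / compared)
}

# Pairwise mismatch statistics over a set of sequences: counts and
# proportions under pairwise deletion of N/- sites. Computed through
# per-base indicator matrices so the all-pairs work runs in BLAS:
# compared(i,j) = resolved_i . resolved_j, matches = sum_b I_b I_b^T.
mismatch_matrices <- function(sequences, labels = NULL) {
  M <- seq_char_matrix(sequences)
  n <- nrow(M)
  match_m <- matrix(0, n, n)
  resolved <- matrix(0, n, ncol(M))
  for (b in c("A", "C", "G", "T")) {
    I <- (M == b) * 1
    match_m <- match_m + tcrossprod(I)
    resolved <- resolved + I
  }
  comp <- tcrossprod(resolved)
  cnt <- comp - match_m
  prop <- ifelse(comp > 0, cnt / comp, NA_real_)
  diag(cnt) <- 0
  diag(prop)[diag(comp) > 0] <- 0
  if (!is.null(labels)) dimnames(cnt) <- dimnames(prop) <- list(labels, labels)
  list(count = cnt, proportion = prop)
}

#' Uncorrected (p) distance matrix between sequences
#'
#' Proportion of mismatched nucleotide sites under pairwise deletion, the
#' distance used for tree building and the among-population divergence
#' statistic.
#'
#' @param sequences Character vector of aligned sequences.
#' @param labels Row/column labels (default names of `sequences`).
#' @return Symmetric numeric matrix.
#' @export
p_distance_matrix <- function(sequences, labels = names(sequences)) {
  mismatch_matrices(sequences, labels)$proportion
}
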