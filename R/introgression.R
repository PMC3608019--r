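#' Flag mitochondrially introgressed individuals
#'
#' An individual is introgressed when the mtDNA lineage of its haplotype
#' differs from its labelled species. Populations are classed `original`
#' (all members original), `introgressed` (all members carry foreign mtDNA)
#' or `mixed` (both present), mirroring the white-circle / colored-star /
#' black-star locality classes of contact-zone maps.
#'
#' @param hapset A [collapse_haplotypes()] result whose `assignment` has been
#'   filled by [assign_lineages()].
#' @return A list with `individuals` (data frame `individual,population,
#'   species,haplotype,lineage,status`) and `populations` (data frame
#'   `population,species,n,n_introgressed,class`).
#' @export
flag_introgression <- function(hapset) {
  if (is.null(hapset$assignment))
    stop("hapset has no lineage assignment; run assign_lineages() first")
  mem <- hapset$members
  lin <- hapset$assignment$lineage[match(mem$haplotype,
                                         hapset$assignment$haplotype)]
  status <- ifelse(lin == mem$species, "original", "introgressed")
  ind <- data.frame(individual = mem$individual, population = mem$population,
                    species = mem$species, haplotype = mem$haplotype,
                    lineage = lin, status = status, stringsAsFactors = FALSE)
  agg_n <- tapply(ind$status, ind$population, length)
  agg_i <- tapply(ind$status == "introgressed", ind$population, sum)
  pops <- data.frame(
    population = names(agg_n),
    species = ind$species[match(names(agg_n), ind$population)],
    n = as.integer(agg_n), n_introgressed = as.integer(agg_i),
    stringsAsFactors = FALSE)
  pops$class <- ifelse(pops$n_introgressed == 0, "original",
                       ifelse(pops$n_introgressed == pops$n, "introgressed",
                              "mixed"))
  rownames(pops) <- NULL
  list(individuals = ind, populations = pops)
}

#' Drop introgressed mtDNA before spatial genetic analysis
#'
#' Two exclusion rules are provided. `"population"` removes every population
#' containing at least one introgressed individual (the retention-count
#' convention of locality-class maps); `"individual"` removes only the
#' introgressed individuals, keeping remaining originals (fully introgressed
#' populations then disappear entirely).
#'
#' @param aln An [mtdna_alignment()].
#' @param flags Result of [flag_introgression()].
#' @param mode `"population"` (default) or `"individual"`.
#' @return The filtered alignment.
#' @export
exclude_introgressed <- function(aln, flags, mode = c("population",
                                                      "individual")) {
  mode <- match.arg(mode)
  if (mode == "population") {
    bad_pops <- flags$populations$population[flags$populations$class !=
                                               "original"]
    keep <- !(aln$population %in% bad_pops)
  } else {
    bad_ind <- flags$individuals$individual[flags$individuals$status ==
                                              "introgressed"]
    keep <- !(aln$individual %in% bad_ind)
  }
  out <- aln[keep, , drop = FALSE]
  attr(out, "aln_length") <- attr(aln, "aln_length")
  class(out) <- class(aln)
  out
}
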