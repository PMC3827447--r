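#' The 12 exemplar taxa of the millipede ordinal-level study set
#'
#' Nine newly sequenced taxa (eight millipedes plus the centipede
#' *Lithobius*), the GenBank EST taxa *Archispirostreptus* and *Ixodes*, and
#' the crustacean reference taxon *Daphnia* retained from the core-ortholog
#' search.
#' @export
STUDY_TAXA <- c("Ixodes", "Daphnia", "Lithobius", "Glomeridesmus",
                "Petaserpes", "Brachycybe", "Abacion", "Cleidogona",
                "Pseudopolydesmus", "Prostemmiulus", "Cambala",
                "Archispirostreptus")

#' Reference millipede ordinal-level topology
#'
#' Returns the rooted 12-taxon tree recovered by the study's Bayesian
#' inference (`method = "bayesian"`, the preferred topology: Stemmiulida
#' sister to Juliformia, Polydesmida sister to that pair), or the
#' maximum-likelihood variant (`method = "ml"`) that instead places the
#' polydesmidan exemplar at the base of the remaining Eugnatha. Both trees
#' resolve Myriapoda, Diplopoda, Helminthomorpha, Colobognatha, Eugnatha,
#' Coelocheta (Callipodida+Chordeumatida) and Juliformia as clades.
#'
#' Branch lengths default to 0.1 throughout: the source analyses publish no
#' usable lengths, and the parsimony reconstructions and topology tests here
#' either ignore lengths or re-optimize them.
#'
#' @param method `"bayesian"` (default) or `"ml"`.
#' @param branch_length length assigned to every edge (default 0.1).
#' @return a rooted [ape::phylo] tree.
#' @export
millipede_topology <- function(method = c("bayesian", "ml"),
                               branch_length = 0.1) {
  method <- match.arg(method)
  nwk <- switch(method,
    bayesian = paste0(
      "(Ixodes,(Daphnia,(Lithobius,(Glomeridesmus,((Petaserpes,Brachycybe),",
      "((Abacion,Cleidogona),(Pseudopolydesmus,(Prostemmiulus,",
      "(Cambala,Archispirostreptus)))))))));"),
    ml = paste0(
      "(Ixodes,(Daphnia,(Lithobius,(Glomeridesmus,((Petaserpes,Brachycybe),",
      "(Pseudopolydesmus,((Abacion,Cleidogona),(Prostemmiulus,",
      "(Cambala,Archispirostreptus)))))))));"))
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(branch_length, nrow(tr$edge))
  tr
}

#' Tip sets defining the named millipede clades on the study topology
#'
#' Convenience lookup used to address internal nodes by clade name via
#' [ape::getMRCA()].
#' @return named list of tip-name character vectors.
#' @export
millipede_clades <- function() {
  list(
    Myriapoda = c("Lithobius", "Glomeridesmus", "Petaserpes", "Brachycybe",
                  "Abacion", "Cleidogona", "Pseudopolydesmus",
                  "Prostemmiulus", "Cambala", "Archispirostreptus"),
    Diplopoda = c("Glomeridesmus", "Petaserpes", "Brachycybe", "Abacion",
                  "Cleidogona", "Pseudopolydesmus", "Prostemmiulus",
                  "Cambala", "Archispirostreptus"),
    Helminthomorpha = c("Petaserpes", "Brachycybe", "Abacion", "Cleidogona",
                        "Pseudopolydesmus", "Prostemmiulus", "Cambala",
                        "Archispirostreptus"),
    Colobognatha = c("Petaserpes", "Brachycybe"),
    Eugnatha = c("Abacion", "Cleidogona", "Pseudopolydesmus",
                 "Prostemmiulus", "Cambala", "Archispirostreptus"),
    Coelocheta = c("Abacion", "Cleidogona"),
    Juliformia = c("Cambala", "Archispirostreptus"))
}

#' Discrete morphological character codings for the exemplar taxa
#'
#' Three characters of millipede evolution, coded discrete and unordered for
#' the order each exemplar represents:
#' \describe{
#'   \item{gonopods}{0 = none, 1 = ninth and tenth leg pairs (Colobognatha),
#'     2 = eighth and ninth leg pairs (Eugnatha).}
#'   \item{ozopores}{0 = none, 1 = lateral defense-secretion pores present.
#'     Coded present for helminthomorph exemplars except *Cleidogona*
#'     (Chordeumatida, the eugnathan order lacking defense secretions).}
#'   \item{spinnerets}{0 = none, 1 = telson spinnerets present
#'     (*Cleidogona*, *Abacion*, *Pseudopolydesmus*, *Prostemmiulus*).}
#' }
#' Outgroup tips (*Ixodes*, *Daphnia*, *Lithobius*) are coded 0 throughout:
#' their lineages lack millipede gonopods, ozopores and spinnerets. The
#' polydesmidan spinneret coding follows reports of functional spinnerets in
#' Polydesmida.
#'
#' @return named list of three [character_matrix()] objects.
#' @export
millipede_characters <- function() {
  z <- stats::setNames(rep(0L, 12L), STUDY_TAXA)
  gon <- z
  gon[c("Petaserpes", "Brachycybe")] <- 1L
  gon[millipede_clades()$Eugnatha] <- 2L
  ozo <- z
  ozo[millipede_clades()$Helminthomorpha] <- 1L
  ozo["Cleidogona"] <- 0L
  spi <- z
  spi[c("Cleidogona", "Abacion", "Pseudopolydesmus", "Prostemmiulus")] <- 1L
  list(
    gonopods = character_matrix("gonopods", gon,
      labels = c("0" = "none", "1" = "leg pairs 9+10",
                 "2" = "leg pairs 8+9")),
    ozopores = character_matrix("ozopores", ozo,
      labels = c("0" = "none", "1" = "present")),
    spinnerets = character_matrix("spinnerets", spi,
      labels = c("0" = "none", "1" = "present")))
}

#' Printed summary counts of the study's data tables
#'
#' The raw-read/processed-read/contig/ortholog counts per sequenced taxon,
#' the pre- and post-optimization supermatrix dimensions, the CEG
#' transcriptome-coverage counts (out of 248 core eukaryotic genes), and the
#' per-taxon locus-inclusion counts, as named constants. These are the
#' published inputs from which all summary percentages in the package's
#' reporting functions can be recomputed.
#'
#' @return nested list with elements `sequencing`, `matrix_pre`,
#'   `matrix_post`, `ceg`, `inclusion`.
#' @export
millipede_study_counts <- function() {
  seq_taxa <- c("Lithobius", "Glomeridesmus", "Petaserpes", "Brachycybe",
                "Pseudopolydesmus", "Prostemmiulus", "Cambala", "Abacion",
                "Cleidogona")
  sequencing <- data.frame(
    taxon = seq_taxa,
    raw_reads = c(63859222, 30728054, 43543711, 34242917, 40382211,
                  41343098, 38623633, 39893805, 29767350),
    processed_reads = c(46366497, 23473057, 32494393, 26009589, 30638665,
                        29259335, 27334077, 30238012, 22288076),
    contigs = c(33692, 20181, 12154, 18570, 18876, 10524, 14071, 15861,
                16572),
    orthologs = c(877, 885, 715, 924, 909, 594, 755, 755, 877))
  ceg <- data.frame(
    taxon = c("Abacion", "Brachycybe", "Cambala", "Cleidogona",
              "Glomeridesmus", "Lithobius", "Petaserpes", "Prostemmiulus",
              "Pseudopolydesmus"),
    complete = c(132, 203, 139, 136, 159, 154, 120, 83, 157),
    partial = c(180, 233, 173, 171, 200, 188, 173, 141, 191))
  incl_taxa <- c("Lithobius", "Glomeridesmus", "Petaserpes", "Brachycybe",
                 "Pseudopolydesmus", "Prostemmiulus", "Cambala", "Abacion",
                 "Cleidogona", "Archispirostreptus", "Ixodes")
  inclusion <- data.frame(
    taxon = incl_taxa,
    pre = c(878, 886, 716, 925, 910, 595, 756, 756, 759, 170, 816),
    post = c(214, 218, 204, 220, 216, 186, 216, 217, 211, 33, 208))
  list(
    sequencing = sequencing,
    matrix_pre = list(n_loci = 1005, n_columns = 532002, n_taxa = 12,
                      n_gap = 1788558, n_missing = 1833905),
    matrix_post = list(n_loci = 221, n_columns = 61641, n_taxa = 12,
                       n_gap = 53286, n_missing = 75146),
    ceg = list(counts = ceg, ceg_total = 248),
    inclusion = inclusion)
}
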