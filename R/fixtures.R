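#' Packaged example data: amino acid transporters in Hemiptera
#'
#' The worked example shipped with the package: copy numbers of the two
#' amino acid transporter superfamilies, APC (amino acid polyamine
#' organocation) and AAAP (amino acid/auxin permease), across 13 insect
#' species, together with a 13-taxon chronogram of those species.
#' Sternorrhyncha — the sap-feeding hemipterans (pea aphid, citrus
#' mealybug, whitefly, potato psyllid) whose obligate endosymbionts
#' provision essential amino acids — are the conventional focal clade
#' for expansion tests on these data.
#'
#' The chronogram reproduces the published tree topology for these taxa
#' (Sternorrhyncha monophyletic; cicada + kissing bug as its sister;
#' body louse sister to Hemiptera; Holometabola as a monophyletic
#' outgroup; within Sternorrhyncha, (aphid, mealybug) with (whitefly,
#' psyllid)). **Its node ages are synthetic placeholders** (root ~390
#' Myr, Sternorrhyncha MRCA ~250 Myr, a plausible Permian-to-present
#' span): exact published ages are not available, so absolute rate
#' estimates on this tree are illustrative, not authoritative.
#'
#' @param name Which fixture: `"chronogram13"` or `"counts_table2"`.
#' @return [hemiptera_chronogram()] returns the `chronogram`;
#'   [transporter_counts()] the count table; [example_fixture()]
#'   dispatches on `name`.
#' @examples
#' tr <- hemiptera_chronogram()
#' counts <- transporter_counts()
#' mrca_branches(tr, sternorrhyncha_taxa(), include_stem = TRUE)
#' @export
hemiptera_chronogram <- function() {
  read_chronogram(system.file("extdata",
                              "hemiptera13_chronogram_synthetic_ages.nwk",
                              package = "famshift", mustWork = TRUE))
}

#' @rdname hemiptera_chronogram
#' @export
transporter_counts <- function() {
  read_counts(system.file("extdata", "transporter_counts.tsv",
                          package = "famshift", mustWork = TRUE),
              tree = hemiptera_chronogram())
}

#' @rdname hemiptera_chronogram
#' @export
sternorrhyncha_taxa <- function() {
  c("Acyrthosiphon_pisum", "Planococcus_citri", "Bemisia_tabaci",
    "Bactericera_cockerelli")
}

#' @rdname hemiptera_chronogram
#' @export
example_fixture <- function(name = c("chronogram13", "counts_table2")) {
  name <- match.arg(name)
  switch(name,
         chronogram13 = hemiptera_chronogram(),
         counts_table2 = transporter_counts())
}
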