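# Built-in fixture networks. Each is stored as its canonical text-format
# document so the on-disk emission, the parsed object and the content hash
# are all pinned to the same bytes.

fixture_texts <- list(

  # Autocatalytic core of the formose cycle: glycolaldehyde condenses with
  # formaldehyde to glyceraldehyde, isomerises to dihydroxyacetone, adds a
  # second formaldehyde to a tetrose which splits into two glycolaldehyde.
  # One turn doubles glycolaldehyde at the cost of two formaldehyde.
  formose = paste(
    "food: formaldehyde",
    "R1: glycolaldehyde + formaldehyde -> glyceraldehyde",
    "R2: glyceraldehyde -> dihydroxyacetone",
    "R3: dihydroxyacetone + formaldehyde -> tetrose",
    "R4: tetrose -> 2 glycolaldehyde",
    sep = "\n"),

  # Reductive citric acid cycle at coarse granularity: citrate cleavage
  # regenerates one oxaloacetate directly while the acetyl branch rebuilds
  # the second via pyruvate and PEP - the asymmetry between the two
  # oxaloacetate molecules produced per turn.
  reductive_tca = paste(
    "food: CO2, red",
    "R1: OAA + red -> SUC",
    "R2: SUC + CO2 + red -> AKG",
    "R3: AKG + CO2 + red -> ICT",
    "R4: ICT -> CIT",
    "R5: CIT -> OAA + ACA",
    "R6: ACA + CO2 + red -> PYR",
    "R7: PYR + CO2 + red -> OAA",
    sep = "\n"),

  # Calvin cycle at sugar-phosphate granularity. Enzymes are represented
  # by an always-available catalyst pool (a food-role species), so every
  # enzymatic step requires it but it never limits ignition - the cycle is
  # analysed "provided that all the obligate enzymes are present".
  # Triose-phosphate isomerase is encoded as two irreversible directions.
  calvin = paste(
    "food: ATP, CO2, Ecalvin, NADPH",
    "waste: ADP, NADP, Pi",
    "R01: RuBP + CO2 -> 2 PGA | cat: Ecalvin",
    "R02: PGA + ATP + NADPH -> GAP + ADP + NADP + Pi | cat: Ecalvin",
    "R03: GAP -> DHAP | cat: Ecalvin",
    "R04: DHAP -> GAP | cat: Ecalvin",
    "R05: GAP + DHAP -> FBP | cat: Ecalvin",
    "R06: FBP -> F6P + Pi | cat: Ecalvin",
    "R07: F6P + GAP -> E4P + X5P | cat: Ecalvin",
    "R08: E4P + DHAP -> SBP | cat: Ecalvin",
    "R09: SBP -> Se7P + Pi | cat: Ecalvin",
    "R10: Se7P + GAP -> R5P + X5P | cat: Ecalvin",
    "R11: R5P -> Ru5P | cat: Ecalvin",
    "R12: X5P -> Ru5P | cat: Ecalvin",
    "R13: Ru5P + ATP -> RuBP + ADP | cat: Ecalvin",
    sep = "\n"),

  # Birds and nests, formal version: A1 the bird, A2 the nesting bird, B
  # the nest. The nest is produced by R1 and required catalytically by R2,
  # whose completion releases two birds. Net of one turn:
  # A1 + x -> 2 A1 + B + y.
  bird_nest = paste(
    "food: x1, x2",
    "waste: y1",
    "R1: A1 + x1 -> A2 + B",
    "R2: A2 + x2 -> 2 A1 + y1 | cat: B",
    sep = "\n"),

  # Birds as simple catalysts of nests: no nest is needed to produce new
  # birds, nests are heterocatalytic products only.
  bird_catalyst = paste(
    "food: x1, x2",
    "waste: y1",
    "R1: x1 -> B | cat: A",
    "R2: A + x2 -> 2 A + y1",
    sep = "\n"),

  # RNA as a true replicator: template replication doubles the molecule.
  rna_only = paste(
    "food: x1",
    "waste: y1",
    "R1: RNA + x1 -> 2 RNA + y1",
    sep = "\n"),

  # Peptides appear as side products of RNA replication and facultatively
  # catalyse it: the catalysed route duplicates the uncatalysed one.
  rna_protein_facultative = paste(
    "food: x1",
    "waste: y1",
    "R1: RNA + x1 -> 2 RNA + P + y1",
    "R2: RNA + x1 -> 2 RNA + P + y1 | cat: P",
    sep = "\n"),

  # Gene-enzyme system with fully obligate coupling: neither nucleic acid
  # nor enzyme can be reproduced without the other.
  rna_protein_obligate = paste(
    "food: x1, x2",
    "waste: y1, z1",
    "R1: DNA + x1 -> 2 DNA + y1 | cat: E",
    "R2: x2 -> E + z1 | cat: DNA + E",
    sep = "\n")
)

# Content hashes of the canonical written form of every fixture, frozen so
# that accidental edits to the encodings are caught by the test suite.
fixture_hash_pins <- c(
  formose = "ee2b147f", reductive_tca = "6d678a75",
  calvin = "f4cf3d90", bird_nest = "c8458982",
  bird_catalyst = "3ca371cd", rna_only = "bb6f2ba3",
  rna_protein_facultative = "1922ce3d", rna_protein_obligate = "7f14fe10"
)

#' Built-in fixture networks
#'
#' Eight small reaction networks used throughout the package: the
#' autocatalytic core of the formose cycle, the reductive citric acid
#' cycle, the Calvin cycle at sugar-phosphate granularity, the bird--nest
#' cycle (both the simple-catalyst and the nesting-bird form), and three
#' nucleic-acid/protein systems (RNA alone, facultative peptide catalysis,
#' obligate gene--enzyme coupling).
#'
#' @param name one of `fixture_names()`.
#' @return A validated [reaction_network()].
#' @examples
#' fixture_names()
#' fixture("bird_nest")
#' @export
fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(fixture_texts))
    stop("unknown fixture '", name, "'; see fixture_names()")
  net <- parse_network(fixture_texts[[name]])
  pin <- fixture_hash_pins[[name]]
  if (!is.na(pin) && network_hash(net) != pin)
    stop("fixture '", name, "' does not match its pinned content hash")
  net
}

#' @rdname fixture
#' @export
fixture_names <- function() names(fixture_texts)

#' Write all fixtures to a directory
#'
#' Emits every built-in network as a `.net` text file plus the standard
#' genetic code as `codons.tsv`. Files are byte-stable across calls and
#' platforms.
#'
#' @param dir a writable directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
emit_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in fixture_names()) {
    p <- file.path(dir, paste0(nm, ".net"))
    write_network(fixture(nm), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "codons.tsv")
  utils::write.table(codon_entities(), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p))
}

# Standard (nuclear) genetic code, frozen in-repo. "*" is the stop signal.
standard_genetic_code <- c(
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

#' The 64 codons as an entity set
#'
#' The standard genetic code as a tabular entity set: each codon is an
#' entity whose feature vector is its three bases and whose natural
#' phenotype under translation is the encoded amino acid (`"*"` for the
#' stop signal). Used as the worked fixture for selection-as-partitioning:
#' translation maps 64 codons onto 20 amino-acid classes plus stop, and
#' codons such as UCA and AGU (here in DNA alphabet: TCA, AGT) are
#' distinct entities with identical phenotypes.
#'
#' @param rna use the RNA alphabet (`U` instead of `T`) for ids and
#'   features; default `FALSE` (DNA alphabet).
#' @return A tibble with columns `id`, `b1`, `b2`, `b3` (the three bases)
#'   and `amino_acid`.
#' @examples
#' codons <- codon_entities(rna = TRUE)
#' codons[codons$id %in% c("UCA", "AGU"), ]
#' @export
codon_entities <- function(rna = FALSE) {
  ids <- names(standard_genetic_code)
  aa <- unname(standard_genetic_code)
  if (rna) ids <- gsub("T", "U", ids, fixed = TRUE)
  m <- do.call(rbind, strsplit(ids, ""))
  tibble::tibble(id = ids, b1 = m[, 1], b2 = m[, 2], b3 = m[, 3],
                 amino_acid = aa)
}
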