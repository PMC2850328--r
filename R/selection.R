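# Selection as a sorting/equivalence formalism: a phenotype function
# induces a partition of an entity set, and two entities are equivalent
# exactly when a given selective force cannot sort between them better
# than random - when their phenotypes are equal.

# Resolve a phenotype specification against an entity tibble: either a
# column name or a function applied to each entity (row, as a named
# list). Returns the vector of phenotype values, with totality enforced.
eval_phenotype <- function(entities, phenotype) {
  stopifnot(is.data.frame(entities), "id" %in% names(entities))
  if (is.character(phenotype) && length(phenotype) == 1L) {
    if (!phenotype %in% names(entities))
      stop("phenotype column '", phenotype, "' not found")
    vals <- entities[[phenotype]]
    name <- phenotype
  } else if (is.function(phenotype)) {
    vals <- vapply(seq_len(nrow(entities)), function(i) {
      v <- phenotype(as.list(entities[i, ]))
      if (is.null(v) || length(v) != 1L) return(NA_character_)
      as.character(v)
    }, character(1))
    name <- "phenotype"
  } else {
    stop("phenotype must be a column name or a function of an entity")
  }
  if (anyNA(vals)) {
    bad <- entities$id[is.na(vals)]
    stop("phenotype is not total: undefined for ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  list(values = as.character(vals), name = name)
}

#' Partition an entity set by phenotype
#'
#' Selection sorts entities by a function of the entities - the
#' phenotype - and thereby partitions the set into equivalence classes:
#' two entities share a block exactly when their phenotypes are equal.
#' Blocks are ordered by their smallest member id, so the partition is
#' deterministic.
#'
#' @param entities a data frame with an `id` column (unique) and
#'   arbitrary feature columns.
#' @param phenotype a column name, or a function taking one entity (a
#'   named list of its row) and returning a single comparable value. Use
#'   a quantising wrapper for approximate real-valued phenotypes.
#' @return An object of class `phenotype_partition`; [tidy()] gives the
#'   membership tibble (`id`, `phenotype`, `block`), [glance()] a
#'   one-row summary.
#' @examples
#' codons <- codon_entities(rna = TRUE)
#' part <- partition_by_phenotype(codons, "amino_acid")
#' glance(part)
#' @export
partition_by_phenotype <- function(entities, phenotype) {
  if (anyDuplicated(entities$id)) stop("entity ids must be unique")
  ph <- eval_phenotype(entities, phenotype)
  ids_chr <- as.character(entities$id)
  first_id <- tapply(ids_chr, ph$values, function(x) sort_c(x)[1])
  block_order <- names(first_id)[order(unname(first_id), method = "radix")]
  block <- match(ph$values, block_order)
  membership <- tibble::tibble(id = as.character(entities$id),
                               phenotype = ph$values, block = block)
  blocks <- lapply(seq_along(block_order), function(b) membership$id[block == b])
  structure(list(membership = membership, blocks = blocks,
                 phenotype_name = ph$name),
            class = "phenotype_partition")
}

#' @export
print.phenotype_partition <- function(x, ...) {
  cat("<phenotype_partition> ", nrow(x$membership), " entities in ",
      length(x$blocks), " classes (phenotype: ", x$phenotype_name, ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy phenotype_partition
#' @export
tidy.phenotype_partition <- function(x, ...) x$membership

#' @method glance phenotype_partition
#' @export
glance.phenotype_partition <- function(x, ...) {
  tibble::tibble(n_entities = nrow(x$membership),
                 n_classes = length(x$blocks),
                 phenotype = x$phenotype_name)
}

#' Are two entities equivalent under a selective force?
#'
#' True exactly when the phenotypes are equal - selection cannot sort
#' between the entities better than random. UCA and AGU are completely
#' different codons, but both code for serine and so are equivalent
#' under translation.
#'
#' @inheritParams partition_by_phenotype
#' @param id1,id2 entity ids.
#' @return Logical.
#' @examples
#' codons <- codon_entities(rna = TRUE)
#' are_equivalent(codons, "UCA", "AGU", "amino_acid")  # TRUE, both serine
#' are_equivalent(codons, "UCA", "UGA", "amino_acid")  # FALSE, UGA is stop
#' @export
are_equivalent <- function(entities, id1, id2, phenotype) {
  ph <- eval_phenotype(entities, phenotype)
  i1 <- match(id1, entities$id)
  i2 <- match(id2, entities$id)
  if (is.na(i1) || is.na(i2)) stop("unknown entity id")
  ph$values[i1] == ph$values[i2]
}

#' Count phenotype classes
#'
#' The number of equivalence classes a phenotype induces, optionally
#' excluding some classes (for instance the stop class of the genetic
#' code: 64 codons map to 20 amino-acid classes plus stop).
#'
#' @inheritParams partition_by_phenotype
#' @param exclude phenotype values whose classes are not counted.
#' @return An integer.
#' @examples
#' codons <- codon_entities()
#' count_phenotype_classes(codons, "amino_acid")                  # 21
#' count_phenotype_classes(codons, "amino_acid", exclude = "*")   # 20
#' @export
count_phenotype_classes <- function(entities, phenotype, exclude = NULL) {
  if (nrow(entities) == 0L) return(0L)
  ph <- eval_phenotype(entities, phenotype)
  vals <- unique(ph$values)
  length(setdiff(vals, exclude))
}

#' Is an entity set a unit of selection?
#'
#' A population is a unit of selection when its members are not all
#' equivalent - when the phenotype partitions it into at least two
#' classes. Two bacterial strains growing logarithmically with different
#' division times are under selection even though nothing dies; a
#' diverse population of exact replicators with different rates is
#' selectable despite having no evolutionary potential.
#'
#' @inheritParams partition_by_phenotype
#' @return Logical.
#' @export
is_unit_of_selection <- function(entities, phenotype) {
  stopifnot(nrow(entities) >= 1L)
  count_phenotype_classes(entities, phenotype) >= 2L
}

#' Genotype--phenotype feature map
#'
#' Describes which features of an entity's information vector determine
#' the genotype and which determine the phenotype: `g(e) = h(e[G_idx])`
#' and `p(e) = f(e[P_idx])`. Richer dependencies are expressed by letting
#' the two index sets overlap.
#'
#' @param g_idx integer indices of genotype-determining features.
#' @param p_idx integer indices of phenotype-determining features.
#' @param h,f optional functions applied to the restricted feature
#'   vectors (default: identity, i.e. the restriction itself).
#' @return An object of class `gp_map`.
#' @export
gp_map <- function(g_idx, p_idx, h = NULL, f = NULL) {
  g_idx <- sort(unique(as.integer(g_idx)))
  p_idx <- sort(unique(as.integer(p_idx)))
  if (any(g_idx < 1L) || any(p_idx < 1L)) stop("feature indices must be >= 1")
  structure(list(g_idx = g_idx, p_idx = p_idx,
                 h = h %||% identity, f = f %||% identity),
            class = "gp_map")
}

#' Are genotype and phenotype decoupled?
#'
#' True when the genotype and phenotype index sets share no feature:
#' then no change to the genotype can alter the phenotype, every
#' genotypic change is neutral from the viewpoint of selection, and
#' selection on phenotypes cannot be channelled toward the genotypes.
#'
#' @param map a [gp_map()].
#' @return Logical.
#' @examples
#' is_decoupled(gp_map(1:2, 3:4))  # TRUE
#' is_decoupled(gp_map(1:3, 3:4))  # FALSE
#' @export
is_decoupled <- function(map) {
  stopifnot(inherits(map, "gp_map"))
  length(intersect(map$g_idx, map$p_idx)) == 0L
}

#' Is an entity set a unit of evolution?
#'
#' A unit of evolution is a unit of selection with a heritable genotype
#' that is linked to the phenotype: the population must have at least
#' two phenotype classes, the heritable fraction must be positive (only
#' informational replicators qualify), and the genotype--phenotype map
#' must not be decoupled.
#'
#' @inheritParams partition_by_phenotype
#' @param map a [gp_map()].
#' @param heredity a [vh_params()] describing the entities.
#' @return Logical.
#' @export
is_unit_of_evolution <- function(entities, phenotype, map, heredity) {
  stopifnot(inherits(map, "gp_map"), inherits(heredity, "vh_params"))
  is_unit_of_selection(entities, phenotype) &&
    heredity$H > 0 &&
    !is_decoupled(map)
}

#' Classify an acquired change
#'
#' The four-way taxonomy of acquired changes by heritability and
#' phenotypic effect:
#' 1. non-heritable neutral, 2. non-heritable effective,
#' 3. heritable neutral, 4. heritable effective.
#' A change is heritable when it touches a heritable feature index and
#' effective when it touches a phenotype-determining index of the map.
#' Whether a heritable neutral change is trivially or non-trivially
#' neutral (altering the mutant phenotype distribution) is not decidable
#' from the indices alone and is accepted as caller-supplied metadata.
#'
#' @param delta_idx integer indices of the changed features.
#' @param map a [gp_map()].
#' @param heritable_idx integer indices of heritable features.
#' @param neutrality optional `"trivial"` or `"nontrivial"` annotation,
#'   recorded (not computed) for quadrant 3.
#' @return A one-row tibble with `quadrant` (1-4), `heritable`,
#'   `effective`, `label`, `neutrality`.
#' @examples
#' m <- gp_map(1:3, 4:6)
#' classify_change(7, m, heritable_idx = 1:3)     # quadrant 1
#' classify_change(4, m, heritable_idx = 1:3)     # quadrant 2
#' classify_change(1, m, heritable_idx = 1:3)     # quadrant 3
#' classify_change(3, gp_map(1:3, 3:4), 1:3)      # quadrant 4
#' @export
classify_change <- function(delta_idx, map, heritable_idx, neutrality = NA) {
  stopifnot(inherits(map, "gp_map"))
  delta_idx <- unique(as.integer(delta_idx))
  heritable_idx <- unique(as.integer(heritable_idx))
  heritable <- length(intersect(delta_idx, heritable_idx)) > 0L
  effective <- length(intersect(delta_idx, map$p_idx)) > 0L
  quadrant <- 1L + 2L * heritable + 1L * effective
  labels <- c("non_heritable_neutral", "non_heritable_effective",
              "heritable_neutral", "heritable_effective")
  tibble::tibble(quadrant = quadrant, heritable = heritable,
                 effective = effective, label = labels[quadrant],
                 neutrality = if (quadrant == 3L) as.character(neutrality)
                              else NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
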