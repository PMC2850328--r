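#' Stoichiometric reaction networks
#'
#' A `reaction_network` holds a small stoichiometric network with
#' designated food (externally supplied, treated as unlimited) and waste
#' (discarded sink) species. Catalysts are a first-class reaction field:
#' a catalyst must be present for the reaction to fire and is returned
#' unchanged, which keeps "obligate catalyst" queries syntactic instead of
#' hiding them in matched reactant/product pairs.
#'
#' @param species a data frame with columns `id`, `name`, `role`
#'   (`"internal"`, `"food"` or `"waste"`).
#' @param reactions a data frame with columns `id` and list-columns
#'   `reactants`, `products`, `catalysts`, each entry a named integer
#'   vector of species counts (possibly empty for `catalysts`).
#' @return A validated object of class `reaction_network` with tibbles
#'   `species` and `reactions` in canonical (id-sorted) order. Any
#'   non-fatal validation findings (for example a food species that is
#'   also produced internally) are recorded in the `"warnings"` attribute.
#' @seealso [parse_network()], [write_network()], [fixture()]
#' @examples
#' net <- parse_network(c(
#'   "food: x",
#'   "R1: A + x -> 2 A"
#' ))
#' net
#' @export
reaction_network <- function(species, reactions) {
  species <- tibble::as_tibble(species)
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("id", "name", "role") %in% names(species)),
            all(c("id", "reactants", "products", "catalysts") %in% names(reactions)))
  species <- species[, c("id", "name", "role")]
  species <- species[order(species$id, method = "radix"), ]
  reactions <- reactions[, c("id", "reactants", "products", "catalysts")]
  reactions <- reactions[order(reactions$id, method = "radix"), ]
  canon <- function(v) {
    v <- v[order(names(v), method = "radix")]
    storage.mode(v) <- "integer"
    v
  }
  reactions$reactants <- lapply(reactions$reactants, canon)
  reactions$products <- lapply(reactions$products, canon)
  reactions$catalysts <- lapply(reactions$catalysts, canon)
  net <- structure(list(species = species, reactions = reactions),
                   class = "reaction_network")
  validate_network(net)
}

validate_network <- function(net) {
  sp <- net$species
  rx <- net$reactions
  warnings <- character(0)
  if (anyDuplicated(sp$id)) stop("duplicate species ids: ",
                                 paste(sp$id[duplicated(sp$id)], collapse = ", "))
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids: ",
                                 paste(rx$id[duplicated(rx$id)], collapse = ", "))
  if (nrow(rx) == 0L) stop("empty network: no reactions")
  bad_role <- setdiff(sp$role, c("internal", "food", "waste"))
  if (length(bad_role)) stop("unknown species role: ", paste(bad_role, collapse = ", "))
  role <- stats::setNames(sp$role, sp$id)
  seen <- character(0)
  for (i in seq_len(nrow(rx))) {
    re <- rx$reactants[[i]]
    pr <- rx$products[[i]]
    ca <- rx$catalysts[[i]]
    refs <- c(names(re), names(pr), names(ca))
    unknown <- setdiff(refs, sp$id)
    if (length(unknown)) stop("reaction ", rx$id[i], " references unknown species: ",
                              paste(unknown, collapse = ", "))
    if (length(re) == 0L && length(ca) == 0L && length(pr) == 0L)
      stop("reaction ", rx$id[i], " is empty")
    if (any(c(re, pr, ca) < 1L)) stop("reaction ", rx$id[i], " has counts < 1")
    both <- intersect(names(re), names(ca))
    if (length(both)) stop("reaction ", rx$id[i], ": species ",
                           paste(both, collapse = ", "),
                           " cannot be both reactant and catalyst")
    wr <- names(c(re, ca))[role[names(c(re, ca))] == "waste"]
    if (length(wr)) stop("reaction ", rx$id[i], ": waste species ",
                         paste(unique(wr), collapse = ", "),
                         " used as reactant or catalyst")
    fp <- names(pr)[role[names(pr)] == "food"]
    if (length(fp)) warnings <- c(warnings, paste0(
      "reaction ", rx$id[i], " produces food species ",
      paste(fp, collapse = ", "), "; food is treated as externally supplied"))
    seen <- c(seen, refs)
  }
  orphan <- setdiff(sp$id, seen)
  if (length(orphan)) stop("species never used in any reaction: ",
                           paste(orphan, collapse = ", "))
  attr(net, "warnings") <- warnings
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  food <- x$species$id[x$species$role == "food"]
  waste <- x$species$id[x$species$role == "waste"]
  if (length(food)) cat("  food:  ", paste(food, collapse = ", "), "\n", sep = "")
  if (length(waste)) cat("  waste: ", paste(waste, collapse = ", "), "\n", sep = "")
  for (i in seq_len(nrow(x$reactions))) {
    cat("  ", format_reaction(x$reactions[i, ]), "\n", sep = "")
  }
  invisible(x)
}

format_side <- function(v) {
  if (length(v) == 0L) return("")
  paste(ifelse(v == 1L, names(v), paste(v, names(v))), collapse = " + ")
}

format_reaction <- function(row) {
  txt <- paste0(row$id, ": ", format_side(row$reactants[[1]]), " -> ",
                format_side(row$products[[1]]))
  ca <- row$catalysts[[1]]
  if (length(ca)) txt <- paste0(txt, " | cat: ", format_side(ca))
  txt
}

#' Parse the reaction-list text format
#'
#' Reads a line-based network document. The grammar is:
#' ```
#' # comment
#' food: x1, x2
#' waste: y1
#' R1: 2 A + x1 -> A2 + B | cat: E
#' ```
#' Coefficients default to 1, species tokens match `[A-Za-z0-9_]+`, and
#' the `| cat:` clause is optional. Species are collected from the
#' reactions; `food:`/`waste:` lines assign roles and may appear anywhere.
#'
#' @param text a character vector of lines, a single string containing
#'   newlines, or the path of an existing file.
#' @return A [reaction_network()].
#' @examples
#' parse_network("R1: A + x -> 2 A + y\nfood: x\nwaste: y")
#' @export
parse_network <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  food <- character(0)
  waste <- character(0)
  ids <- character(0)
  reactants <- list()
  products <- list()
  catalysts <- list()
  tok <- "[A-Za-z0-9_]+"
  parse_side <- function(s, where) {
    s <- trimws(s)
    if (s == "") return(stats::setNames(integer(0), character(0)))
    parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- integer(0)
    for (p in parts) {
      m <- regmatches(p, regexec(paste0("^(?:([0-9]+)\\s+)?(", tok, ")$"), p))[[1]]
      if (length(m) == 0L) stop("parse error at line ", where, ": bad term '", p, "'")
      k <- if (m[2] == "") 1L else as.integer(m[2])
      out[m[3]] <- sum(out[m[3]], k, na.rm = TRUE)
    }
    out
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^food\\s*:", ln)) {
      food <- c(food, trimws(strsplit(sub("^food\\s*:", "", ln), ",")[[1]]))
      next
    }
    if (grepl("^waste\\s*:", ln)) {
      waste <- c(waste, trimws(strsplit(sub("^waste\\s*:", "", ln), ",")[[1]]))
      next
    }
    m <- regmatches(ln, regexec(paste0("^(", tok, ")\\s*:\\s*(.*)$"), ln))[[1]]
    if (length(m) == 0L) stop("parse error at line ", i, ": '", ln, "'")
    rid <- m[2]
    body <- m[3]
    if (rid %in% ids) stop("duplicate reaction id '", rid, "' at line ", i)
    cat_part <- stats::setNames(integer(0), character(0))
    if (grepl("|", body, fixed = TRUE)) {
      halves <- strsplit(body, "|", fixed = TRUE)[[1]]
      if (length(halves) != 2L || !grepl("^\\s*cat\\s*:", halves[2]))
        stop("parse error at line ", i, ": malformed '| cat:' clause")
      cat_part <- parse_side(sub("^\\s*cat\\s*:", "", halves[2]), i)
      body <- halves[1]
    }
    sides <- strsplit(body, "->", fixed = TRUE)[[1]]
    if (length(sides) != 2L) stop("parse error at line ", i, ": expected one '->'")
    ids <- c(ids, rid)
    reactants <- c(reactants, list(parse_side(sides[1], i)))
    products <- c(products, list(parse_side(sides[2], i)))
    catalysts <- c(catalysts, list(cat_part))
  }
  if (length(ids) == 0L) stop("empty network: document contains no reactions")
  used <- unique(unlist(lapply(c(reactants, products, catalysts), names)))
  food <- unique(food[nzchar(food)])
  waste <- unique(waste[nzchar(waste)])
  missing <- setdiff(c(food, waste), used)
  if (length(missing)) stop("food/waste declaration references unknown species: ",
                            paste(missing, collapse = ", "))
  overlap <- intersect(food, waste)
  if (length(overlap)) stop("species declared both food and waste: ",
                            paste(overlap, collapse = ", "))
  role <- stats::setNames(rep("internal", length(used)), used)
  role[food] <- "food"
  role[waste] <- "waste"
  reaction_network(
    species = tibble::tibble(id = used, name = used, role = unname(role[used])),
    reactions = tibble::tibble(id = ids, reactants = reactants,
                               products = products, catalysts = catalysts)
  )
}

#' Write a network in the reaction-list text format
#'
#' The writer emits a deterministic canonical form: a `food:` line, a
#' `waste:` line (each alphabetical, omitted when empty), then reactions
#' sorted by id with species sorted alphabetically within each side.
#' `parse_network(write_network(net))` reproduces `net` exactly.
#'
#' @param net a [reaction_network()].
#' @param path optional file path; when given the text is also written
#'   there.
#' @return The document as a single string, invisibly when `path` is used.
#' @export
write_network <- function(net, path = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  lines <- character(0)
  food <- sort_c(net$species$id[net$species$role == "food"])
  waste <- sort_c(net$species$id[net$species$role == "waste"])
  if (length(food)) lines <- c(lines, paste0("food: ", paste(food, collapse = ", ")))
  if (length(waste)) lines <- c(lines, paste0("waste: ", paste(waste, collapse = ", ")))
  for (i in seq_len(nrow(net$reactions))) {
    lines <- c(lines, format_reaction(net$reactions[i, ]))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Net stoichiometry of a firing vector
#'
#' Sums, over all reactions, the firing count times (products minus
#' reactants). Catalysts are consumed and returned, so they contribute
#' zero net change. This is the "net equation" of a number of turns of a
#' cycle: for the bird--nest fixture, firing each reaction once gives the
#' net A1 + x -> 2 A1 + B + y.
#'
#' @param net a [reaction_network()].
#' @param firing a named integer vector (or two-column data frame
#'   `reaction`, `count`) of non-negative firing counts; reactions not
#'   mentioned fire zero times.
#' @return A tibble with columns `species` and `net` (integer), one row
#'   per species in id order.
#' @examples
#' bn <- fixture("bird_nest")
#' net_stoichiometry(bn, c(R1 = 1, R2 = 1))
#' @export
net_stoichiometry <- function(net, firing) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.data.frame(firing)) {
    firing <- stats::setNames(as.integer(firing$count), firing$reaction)
  }
  if (length(firing) && (is.null(names(firing)) || any(!nzchar(names(firing)))))
    stop("firing vector must be named by reaction id")
  unknown <- setdiff(names(firing), net$reactions$id)
  if (length(unknown)) stop("unknown reaction id in firing vector: ",
                            paste(unknown, collapse = ", "))
  if (any(firing < 0L)) stop("firing counts must be non-negative")
  out <- stats::setNames(integer(nrow(net$species)), net$species$id)
  for (i in seq_len(nrow(net$reactions))) {
    k <- firing[net$reactions$id[i]]
    if (is.na(k) || k == 0L) next
    re <- net$reactions$reactants[[i]]
    pr <- net$reactions$products[[i]]
    out[names(re)] <- out[names(re)] - as.integer(k) * re
    out[names(pr)] <- out[names(pr)] + as.integer(k) * pr
  }
  tibble::tibble(species = names(out), net = unname(out))
}

#' Content hash of a network
#'
#' A 32-bit FNV-1a hash of the canonical written form, used to pin
#' fixtures and to stamp JSON reports. Identical networks always hash
#' identically because [write_network()] is deterministic.
#'
#' @param net a [reaction_network()].
#' @return An 8-character lowercase hex string.
#' @export
network_hash <- function(net) {
  fnv1a32(write_network(net))
}

# locale-independent (byte-order) character sort, so canonical forms and
# content hashes do not depend on LC_COLLATE
sort_c <- function(x) x[order(x, method = "radix")]

fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor only touches the low byte (b < 256); bitwXor cannot take h >= 2^31
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b)
    # h * 16777619 mod 2^32, split into 16-bit halves to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy reaction_network
#' @export
tidy.reaction_network <- function(x, ...) {
  tibble::tibble(
    reaction = x$reactions$id,
    reactants = vapply(x$reactions$reactants, format_side, character(1)),
    products = vapply(x$reactions$products, format_side, character(1)),
    catalysts = vapply(x$reactions$catalysts, format_side, character(1))
  )
}

#' @method glance reaction_network
#' @export
glance.reaction_network <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_reactions = nrow(x$reactions),
    n_food = sum(x$species$role == "food"),
    n_waste = sum(x$species$role == "waste"),
    hash = network_hash(x)
  )
}
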