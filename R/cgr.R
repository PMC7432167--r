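#' Perceive per-atom hybridization labels
#'
#' Assigns one of `"sp3"`, `"sp2"`, `"sp"` or `"aromatic"` to every atom of a
#' molecule graph. Aromatic atoms (from the input aromatic notation) get the
#' dedicated `"aromatic"` label so that an aromatic ring adjacent to a
#' reaction centre can be told apart from an aliphatic one. Aliphatic atoms
#' are labelled from their incident multiple bonds: any triple bond or two or
#' more double bonds gives `"sp"`, exactly one double bond gives `"sp2"`,
#' anything else `"sp3"`.
#'
#' @param molecule a molecule graph as produced by [parse_reaction()].
#' @return character vector of hybridization labels, one per atom.
#' @export
perceive_hybridization <- function(molecule) {
  na <- nrow(molecule$atoms)
  ndou <- ntri <- integer(na)
  naro <- integer(na)
  b <- molecule$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      if (b$order[k] == "double") {
        ndou[b$a1[k]] <- ndou[b$a1[k]] + 1L; ndou[b$a2[k]] <- ndou[b$a2[k]] + 1L
      } else if (b$order[k] == "triple") {
        ntri[b$a1[k]] <- ntri[b$a1[k]] + 1L; ntri[b$a2[k]] <- ntri[b$a2[k]] + 1L
      } else if (b$order[k] == "aromatic") {
        naro[b$a1[k]] <- naro[b$a1[k]] + 1L; naro[b$a2[k]] <- naro[b$a2[k]] + 1L
      }
    }
  }
  out <- rep("sp3", na)
  out[ndou == 1L] <- "sp2"
  out[ntri >= 1L | ndou >= 2L] <- "sp"
  out[molecule$atoms$aromatic | naro > 0L] <- "aromatic"
  out
}

#' Build the Condensed Graph of Reaction
#'
#' Superposes the reactant and product sides of a fully atom-mapped reaction
#' into one graph keyed by atom-map number. Each atom carries its formal
#' charge, heavy-neighbour count and hybridization before and after the
#' transformation; each bond carries its order before and after (`"none"`
#' when the bond exists on one side only). A bond is *dynamic* when its two
#' orders differ; an atom is *dynamic* when its charge, heavy-neighbour count
#' or hybridization changes, or when it is incident to a dynamic bond.
#'
#' @param reaction a [`reaction`] from [parse_reaction()], or a reaction
#'   SMILES string.
#' @return an object of class `cgr`: list with `atoms` (data frame keyed by
#'   `map` with before/after attributes and a `dynamic` flag) and `bonds`
#'   (data frame with map-number endpoints `a1 < a2`, `order_before`,
#'   `order_after`, `dynamic`).
#' @examples
#' g <- build_cgr("[CH3:1][Br:2].[OH-:3]>>[CH3:1][OH:3].[Br-:2]")
#' g$bonds
#' @export
build_cgr <- function(reaction) {
  if (is.character(reaction)) reaction <- parse_reaction(reaction)
  stopifnot(inherits(reaction, "reaction"))
  side_info <- function(mols) {
    at <- list(); bd <- list()
    for (m in mols) {
      hyb <- perceive_hybridization(m)
      deg <- tabulate(c(m$bonds$a1, m$bonds$a2), nbins = nrow(m$atoms))
      at[[length(at) + 1L]] <- data.frame(
        map = m$atoms$map, element = m$atoms$element, charge = m$atoms$charge,
        nb = deg, hyb = hyb, stringsAsFactors = FALSE)
      if (nrow(m$bonds)) {
        m1 <- m$atoms$map[m$bonds$a1]; m2 <- m$atoms$map[m$bonds$a2]
        bd[[length(bd) + 1L]] <- data.frame(
          a1 = pmin(m1, m2), a2 = pmax(m1, m2), order = m$bonds$order,
          stringsAsFactors = FALSE)
      }
    }
    list(atoms = do.call(rbind, at),
         bonds = if (length(bd)) do.call(rbind, bd) else
           data.frame(a1 = integer(0), a2 = integer(0), order = character(0)))
  }
  before <- side_info(reaction$reactants)
  after  <- side_info(reaction$products)
  ob <- before$atoms[order(before$atoms$map), ]
  oa <- after$atoms[order(after$atoms$map), ]
  if (!identical(ob$map, oa$map))
    stop("mapping error: atom-map sets differ between sides", call. = FALSE)
  mism <- ob$map[ob$element != oa$element]
  if (length(mism))
    stop("inconsistent mapping: element changes for map number(s) ",
         paste(mism, collapse = ", "), call. = FALSE)
  atoms <- data.frame(
    map = ob$map, element = ob$element,
    charge_before = ob$charge, charge_after = oa$charge,
    nb_before = ob$nb, nb_after = oa$nb,
    hyb_before = ob$hyb, hyb_after = oa$hyb,
    stringsAsFactors = FALSE)
  bkey <- function(b) paste(b$a1, b$a2, sep = "-")
  kb <- bkey(before$bonds); ka <- bkey(after$bonds)
  allk <- sort(union(kb, ka))
  order_b <- before$bonds$order[match(allk, kb)]
  order_a <- after$bonds$order[match(allk, ka)]
  order_b[is.na(order_b)] <- "none"
  order_a[is.na(order_a)] <- "none"
  ep <- do.call(rbind, strsplit(allk, "-", fixed = TRUE))
  bonds <- data.frame(
    a1 = if (length(allk)) as.integer(ep[, 1]) else integer(0),
    a2 = if (length(allk)) as.integer(ep[, 2]) else integer(0),
    order_before = order_b, order_after = order_a,
    stringsAsFactors = FALSE)
  bonds$dynamic <- bonds$order_before != bonds$order_after
  dyn_atom <- with(atoms, charge_before != charge_after |
                     nb_before != nb_after | hyb_before != hyb_after)
  if (any(bonds$dynamic)) {
    dmaps <- unique(c(bonds$a1[bonds$dynamic], bonds$a2[bonds$dynamic]))
    dyn_atom[atoms$map %in% dmaps] <- TRUE
  }
  atoms$dynamic <- dyn_atom
  # deterministic order regardless of input atom order
  atoms <- atoms[order(atoms$map), ]
  bonds <- bonds[order(bonds$a1, bonds$a2), ]
  rownames(atoms) <- rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds), class = "cgr")
}

#' @export
print.cgr <- function(x, ...) {
  cat(sprintf("<cgr> %d atoms (%d dynamic), %d bonds (%d dynamic)\n",
              nrow(x$atoms), sum(x$atoms$dynamic),
              nrow(x$bonds), sum(x$bonds$dynamic)))
  invisible(x)
}

#' Find reaction centres of a CGR
#'
#' A reaction centre is a connected component of the subgraph induced by the
#' dynamic atoms of the CGR, using the CGR bonds that join two dynamic atoms
#' (dynamic bonds always qualify). Centres are returned in deterministic
#' order, sorted by their smallest atom-map number. A change-free CGR has no
#' centres.
#'
#' @param cgr a [`cgr`] object (or reaction / reaction SMILES, coerced).
#' @return list of centres; each centre is a list with `atoms` (map numbers)
#'   and `bonds` (row indices into `cgr$bonds`).
#' @export
find_reaction_centers <- function(cgr) {
  cgr <- as_cgr(cgr)
  dyn <- cgr$atoms$map[cgr$atoms$dynamic]
  if (!length(dyn)) return(list())
  sub <- which(cgr$bonds$a1 %in% dyn & cgr$bonds$a2 %in% dyn)
  comp <- setNames(seq_along(dyn), dyn)  # union-find via repeated relabel
  for (k in sub) {
    c1 <- comp[as.character(cgr$bonds$a1[k])]
    c2 <- comp[as.character(cgr$bonds$a2[k])]
    if (c1 != c2) comp[comp == c2] <- c1
  }
  groups <- split(dyn, comp[as.character(dyn)])
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  lapply(unname(groups), function(g) {
    list(atoms = sort(g),
         bonds = which(cgr$bonds$a1 %in% g & cgr$bonds$a2 %in% g))
  })
}

as_cgr <- function(x) {
  if (inherits(x, "cgr")) x else build_cgr(x)
}
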