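#' Parse an atom-mapped reaction SMILES string
#'
#' Parses a reaction written in the daylight dialect
#' `reactants>agents>products` (or `reactants>>products`; the agents field, if
#' present, is ignored) into a [`reaction`] object. Every heavy atom must
#' carry an atom-map number, and the multiset of map numbers must be identical
#' on the two sides: atom maps are the sole atom correspondence used
#' downstream, no automatic atom-to-atom mapping is attempted.
#'
#' Supported SMILES features: bracket atoms with element, charge, explicit H
#' count and map number; the organic subset (`B C N O P S F Cl Br I`) and its
#' aromatic lowercase forms; bonds `-`, `=`, `#`, `:` (aromatic); branches;
#' ring-bond closures (including `%nn`); `.`-separated components.
#' Aromaticity is taken from the input notation (lowercase atoms / `:` bonds)
#' and checked for ring validity; no independent aromatizer is applied.
#' Stereochemistry and isotopes are ignored.
#'
#' @param text a single reaction SMILES string.
#' @return an object of class `reaction`: a list with elements `reactants` and
#'   `products`, each a list of molecule graphs (atom table with `element`,
#'   `aromatic`, `charge`, `hcount`, `map`; bond table with `a1`, `a2`,
#'   `order`).
#' @examples
#' rx <- parse_reaction("[CH3:1][Br:2].[OH-:3]>>[CH3:1][OH:3].[Br-:2]")
#' rx
#' @export
parse_reaction <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("parse error: reaction SMILES must be a single nonempty string", call. = FALSE)
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  # "a>>b" splits into c("a", "", "b"); "a>c>b" into c("a", "c", "b")
  if (length(parts) != 3L)
    stop("parse error: expected 'reactants>>products' (or 'reactants>agents>products') in ",
         sQuote(text), call. = FALSE)
  if (!nzchar(parts[1]) || !nzchar(parts[3]))
    stop("parse error: empty reactant or product side in ", sQuote(text), call. = FALSE)
  reactants <- lapply(strsplit(parts[1], ".", fixed = TRUE)[[1]], parse_smiles)
  products  <- lapply(strsplit(parts[3], ".", fixed = TRUE)[[1]], parse_smiles)
  rx <- structure(list(reactants = reactants, products = products), class = "reaction")
  validate_mapping(rx)
  rx
}

#' @export
print.reaction <- function(x, ...) {
  nr <- length(x$reactants); np <- length(x$products)
  na <- sum(vapply(x$reactants, function(m) nrow(m$atoms), integer(1)))
  cat(sprintf("<reaction> %d reactant(s), %d product(s), %d mapped heavy atoms\n",
              nr, np, na))
  invisible(x)
}

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

# Parse one molecule SMILES into list(atoms = data.frame, bonds = data.frame).
parse_smiles <- function(s) {
  if (!nzchar(s)) stop("parse error: empty molecule SMILES", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list()   # each: list(element, aromatic, charge, hcount, map)
  bonds <- list()   # each: list(a1, a2, order)
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NA_character_
  ring <- list()    # ring closure digit -> list(atom, bond)
  i <- 1L
  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- resolve_order(pending_bond, atoms[[prev]]$aromatic && a$aromatic)
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx, order = ord)
    }
    pending_bond <<- NA_character_
    prev <<- idx
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("parse error: unclosed bracket atom in ", sQuote(s), call. = FALSE)
      add_atom(parse_bracket_atom(substr(s, i + 1L, j - 1L), s))
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("parse error: branch before any atom in ", sQuote(s), call. = FALSE)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("parse error: unbalanced ')' in ", sQuote(s), call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("parse error: bad ring closure in ", sQuote(s), call. = FALSE)
        key <- substr(s, i + 1L, i + 2L)
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.na(prev)) stop("parse error: ring closure before any atom in ", sQuote(s), call. = FALSE)
      if (!is.null(ring[[key]])) {
        op <- ring[[key]]
        ord <- if (!is.na(pending_bond)) pending_bond
               else if (!is.na(op$bond)) op$bond
               else NA_character_
        ordc <- resolve_order(ord, atoms[[op$atom]]$aromatic && atoms[[prev]]$aromatic)
        if (op$atom == prev)
          stop("parse error: ring closure self-loop in ", sQuote(s), call. = FALSE)
        bonds[[length(bonds) + 1L]] <- list(a1 = op$atom, a2 = prev, order = ordc)
        ring[[key]] <- NULL
        pending_bond <- NA_character_
      } else {
        ring[[key]] <- list(atom = prev, bond = pending_bond)
        pending_bond <- NA_character_
      }
    } else {
      # organic-subset atom, possibly two-letter
      two <- if (i < n) substr(s, i, i + 1L) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_, map = NA_integer_))
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(list(element = ch, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_, map = NA_integer_))
        i <- i + 1L
      } else if (ch %in% AROMATIC_ORGANIC) {
        add_atom(list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                      hcount = NA_integer_, map = NA_integer_))
        i <- i + 1L
      } else {
        stop("parse error: unexpected character ", sQuote(ch), " in ", sQuote(s),
             call. = FALSE)
      }
    }
  }
  if (length(stack)) stop("parse error: unbalanced '(' in ", sQuote(s), call. = FALSE)
  if (length(ring)) stop("parse error: unmatched ring closure in ", sQuote(s), call. = FALSE)
  if (!length(atoms)) stop("parse error: no atoms in ", sQuote(s), call. = FALSE)
  adf <- data.frame(
    element  = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge   = vapply(atoms, `[[`, integer(1), "charge"),
    hcount   = vapply(atoms, `[[`, integer(1), "hcount"),
    map      = vapply(atoms, `[[`, integer(1), "map"),
    stringsAsFactors = FALSE
  )
  if (length(bonds)) {
    bdf <- data.frame(
      a1 = vapply(bonds, `[[`, integer(1), "a1"),
      a2 = vapply(bonds, `[[`, integer(1), "a2"),
      order = vapply(bonds, `[[`, character(1), "order"),
      stringsAsFactors = FALSE
    )
    key <- paste(pmin(bdf$a1, bdf$a2), pmax(bdf$a1, bdf$a2))
    if (anyDuplicated(key))
      stop("parse error: duplicate bond in ", sQuote(s), call. = FALSE)
  } else {
    bdf <- data.frame(a1 = integer(0), a2 = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  }
  mol <- list(atoms = adf, bonds = bdf)
  check_aromatic_rings(mol, s)
  mol
}

resolve_order <- function(sym, both_aromatic) {
  if (is.na(sym)) return(if (both_aromatic) "aromatic" else "single")
  switch(sym,
         "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
         stop("parse error: unknown bond symbol ", sQuote(sym), call. = FALSE))
}

parse_bracket_atom <- function(body, s) {
  rest <- body
  # isotope (ignored)
  rest <- sub("^[0-9]+", "", rest)
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|b|c|n|o|p|s|se|as)", rest))
  if (!length(m) || !nzchar(m))
    stop("parse error: bad bracket atom [", body, "] in ", sQuote(s), call. = FALSE)
  elem <- m
  rest <- substr(rest, nchar(elem) + 1L, nchar(rest))
  aromatic <- elem %in% c(AROMATIC_ORGANIC, "se", "as")
  element <- if (aromatic) paste0(toupper(substr(elem, 1, 1)), substr(elem, 2, 10)) else elem
  # chirality (ignored)
  rest <- sub("^@{1,2}", "", rest)
  # explicit hydrogens
  hcount <- 0L
  hm <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(hm) && nzchar(hm)) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substr(hm, 2, nchar(hm)))
    rest <- substr(rest, nchar(hm) + 1L, nchar(rest))
  }
  # charge: +, -, ++, --, +2, -2, +0 ...
  charge <- 0L
  cm <- regmatches(rest, regexpr("^(\\+{1,3}|-{1,3})([0-9]+)?", rest))
  if (length(cm) && nzchar(cm)) {
    sign <- if (substr(cm, 1, 1) == "+") 1L else -1L
    digs <- gsub("[+-]", "", cm)
    charge <- if (nzchar(digs)) sign * as.integer(digs) else sign * nchar(cm)
    rest <- substr(rest, nchar(cm) + 1L, nchar(rest))
  }
  map <- NA_integer_
  mm <- regmatches(rest, regexpr("^:[0-9]+", rest))
  if (length(mm) && nzchar(mm)) {
    map <- as.integer(substr(mm, 2, nchar(mm)))
    rest <- substr(rest, nchar(mm) + 1L, nchar(rest))
  }
  if (nzchar(rest))
    stop("parse error: trailing ", sQuote(rest), " in bracket atom [", body, "]",
         call. = FALSE)
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount, map = map)
}

# Every aromatic atom must sit in a cycle of the aromatic-bond subgraph.
check_aromatic_rings <- function(mol, s) {
  ar <- which(mol$atoms$aromatic)
  if (!length(ar)) return(invisible(TRUE))
  ab <- mol$bonds[mol$bonds$order == "aromatic", , drop = FALSE]
  deg <- tabulate(c(ab$a1, ab$a2), nbins = nrow(mol$atoms))
  bad <- ar[deg[ar] < 2L]
  if (length(bad))
    stop("parse error: aromatic atom(s) not in an aromatic ring in ", sQuote(s),
         call. = FALSE)
  invisible(TRUE)
}

validate_mapping <- function(rx) {
  side_maps <- function(side, name) {
    maps <- integer(0)
    for (m in side) {
      mm <- m$atoms$map
      if (anyNA(mm))
        stop("mapping error: unmapped heavy atom(s) on ", name, " side", call. = FALSE)
      maps <- c(maps, mm)
    }
    if (anyDuplicated(maps))
      stop("mapping error: duplicated atom-map number(s) ",
           paste(unique(maps[duplicated(maps)]), collapse = ", "),
           " on ", name, " side", call. = FALSE)
    maps
  }
  rm_ <- side_maps(rx$reactants, "reactant")
  pm_ <- side_maps(rx$products, "product")
  only_r <- setdiff(rm_, pm_)
  only_p <- setdiff(pm_, rm_)
  if (length(only_r) || length(only_p))
    stop("mapping error: unbalanced atom maps; ",
         if (length(only_r)) paste0("only in reactants: ",
                                    paste(sort(only_r), collapse = ", "), "; ") else "",
         if (length(only_p)) paste0("only in products: ",
                                    paste(sort(only_p), collapse = ", ")) else "",
         call. = FALSE)
  invisible(TRUE)
}
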