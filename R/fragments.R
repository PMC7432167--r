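#' Enumerate linear fragment descriptors of a CGR
#'
#' Counts all simple linear paths of the CGR with `min_atoms` to `max_atoms`
#' atoms. A path and its reversal are the same occurrence; each fragment is
#' keyed by the lexicographic minimum of its forward and reversed
#' serializations. Atom tokens are element symbols; bond tokens are
#' `order_before>>order_after`, so fragments crossing dynamic bonds are
#' distinct descriptors from their static counterparts, while per-atom charge
#' or hybridization changes (as in zwitterion-type tautomerism, which has no
#' dynamic bonds) do not create new fragments.
#'
#' @param cgr a [`cgr`] object (or reaction / reaction SMILES, coerced).
#' @param min_atoms,max_atoms path length bounds in atoms (defaults 2 and 4).
#' @return named integer vector: canonical fragment string -> occurrence count.
#' @examples
#' enumerate_fragments("[CH3:1][CH3:2]>>[CH3:1][CH3:2]")
#' @export
enumerate_fragments <- function(cgr, min_atoms = 2L, max_atoms = 4L) {
  stopifnot(min_atoms >= 2L, max_atoms >= min_atoms)
  cgr <- as_cgr(cgr)
  maps <- cgr$atoms$map
  n <- length(maps)
  elem <- cgr$atoms$element
  adj <- vector("list", n)
  btok <- bond_token(cgr$bonds)
  b1 <- match(cgr$bonds$a1, maps); b2 <- match(cgr$bonds$a2, maps)
  for (k in seq_along(b1)) {
    adj[[b1[k]]] <- rbind(adj[[b1[k]]], c(b2[k], k))
    adj[[b2[k]]] <- rbind(adj[[b2[k]]], c(b1[k], k))
  }
  counts <- new.env(parent = emptyenv())
  bump <- function(key) {
    assign(key, (if (exists(key, counts, inherits = FALSE)) get(key, counts) else 0L) + 1L,
           counts)
  }
  path_string <- function(vpath, bpath) {
    fwd <- character(2L * length(vpath) - 1L)
    fwd[seq(1L, length(fwd), by = 2L)] <- elem[vpath]
    if (length(bpath)) fwd[seq(2L, length(fwd), by = 2L)] <- btok[bpath]
    s1 <- paste(fwd, collapse = "*")
    s2 <- paste(rev(fwd), collapse = "*")
    if (s1 <= s2) s1 else s2
  }
  walk <- function(vpath, bpath) {
    len <- length(vpath)
    if (len >= min_atoms && maps[vpath[1L]] < maps[vpath[len]])
      bump(path_string(vpath, bpath))
    if (len == max_atoms) return(invisible(NULL))
    nb <- adj[[vpath[len]]]
    if (is.null(nb)) return(invisible(NULL))
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1L]
      if (!(v %in% vpath)) walk(c(vpath, v), c(bpath, nb[r, 2L]))
    }
    invisible(NULL)
  }
  for (v in seq_len(n)) walk(v, integer(0))
  keys <- sort(ls(counts))
  out <- vapply(keys, function(k) get(k, counts), integer(1))
  names(out) <- keys
  out
}
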