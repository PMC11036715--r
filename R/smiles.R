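# SMILES reader/writer for the daylight organic subset plus bracket atoms
# (charge, explicit H, @/@@ tetrahedral marks, atom-map numbers), ring
# closures (incl. %nn), branches and dot-separated components.  Isotopes
# and directional (/ \) stereo bonds are out of scope; / and \ are read as
# single bonds.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_ok <- c("b", "c", "n", "o", "p", "s", "se", "as")

# daylight normal-valence states used for implicit hydrogen filling
.valence_states <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = c(1, 3, 5, 7), Br = c(1, 3, 5, 7), I = c(1, 3, 5, 7)
)

.bond_order_num <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

.implicit_h <- function(symbol, bond_sum, charge = 0L) {
  states <- .valence_states[[symbol]]
  if (is.null(states) || charge != 0L) return(0L)
  st <- states[states >= bond_sum - 1e-9]
  if (!length(st)) return(0L)
  max(0L, as.integer(floor(st[1] - bond_sum + 1e-9)))
}

#' Parse a SMILES string into a molecular graph
#'
#' Hydrogens are implicit: only heavy atoms become nodes, with hydrogen
#' counts recorded per atom (explicit `H` counts inside brackets, daylight
#' normal-valence filling otherwise).  Atom-map numbers (`[CH3:5]`) are
#' preserved as metadata.  Atom indices follow the order of appearance in
#' the string.
#'
#' @param smiles a single SMILES string (may contain `.`-separated
#'   components)
#' @return a [molgraph] object
#' @examples
#' g <- parse_smiles("c1ccccc1O")
#' g$atom_count
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES string", call. = FALSE)
  n_max <- nchar(s)
  sym <- character(0); arom <- logical(0); chg <- integer(0)
  nh <- integer(0); chir <- character(0); mapno <- integer(0)
  has_bracket_h <- logical(0)
  bi <- integer(0); bj <- integer(0); bord <- character(0)

  pos <- 1L
  prev <- NA_integer_
  pending <- NA_character_   # explicit bond symbol awaiting next atom
  stack <- integer(0)
  ring <- list()             # digit label -> list(atom, bond)

  peek <- function(k = 0L) if (pos + k <= n_max) substr(s, pos + k, pos + k) else ""

  add_atom <- function(symbol, aromatic, charge, n_h, chirality, map, expl_h) {
    sym[length(sym) + 1L] <<- symbol
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    nh[length(nh) + 1L] <<- n_h
    chir[length(chir) + 1L] <<- chirality
    mapno[length(mapno) + 1L] <<- map
    has_bracket_h[length(has_bracket_h) + 1L] <<- expl_h
    length(sym)
  }

  add_bond <- function(i, j, explicit) {
    ord <- explicit
    if (is.na(ord)) ord <- if (arom[i] && arom[j]) "aromatic" else "single"
    if (i == j) stop("ring-closure bond to self in SMILES '", s, "'", call. = FALSE)
    bi[length(bi) + 1L] <<- i; bj[length(bj) + 1L] <<- j
    bord[length(bord) + 1L] <<- ord
  }

  close_or_open_ring <- function(label) {
    key <- as.character(label)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, bond = pending)
    } else {
      open <- ring[[key]]
      expl <- if (!is.na(pending)) pending else open$bond
      add_bond(open$atom, prev, expl)
      ring[[key]] <<- NULL
    }
    pending <<- NA_character_
  }

  while (pos <= n_max) {
    ch <- peek()
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                        ":" = "aromatic", "/" = "single", "\\" = "single")
      pos <- pos + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES '", s, "'", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_character_; pos <- pos + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) stop("ring closure before any atom in '", s, "'", call. = FALSE)
      if (ch == "%") {
        lab <- substr(s, pos + 1L, pos + 2L)
        if (!grepl("^[0-9]{2}$", lab))
          stop("malformed %nn ring closure in '", s, "'", call. = FALSE)
        pos <- pos + 3L
      } else {
        lab <- ch; pos <- pos + 1L
      }
      close_or_open_ring(lab)
    } else if (ch == "[") {
      close_pos <- regexpr("]", substr(s, pos, n_max), fixed = TRUE)
      if (close_pos < 0) stop("unclosed '[' in SMILES '", s, "'", call. = FALSE)
      body <- substr(s, pos + 1L, pos + close_pos - 2L)
      pos <- pos + close_pos
      m <- regexec(
        "^([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:([0-9]+))?$",
        body)
      parts <- regmatches(body, m)[[1]]
      if (!length(parts))
        stop("cannot parse bracket atom '[", body, "]' in SMILES '", s, "'",
             call. = FALSE)
      raw_sym <- parts[2]
      aromatic <- raw_sym %in% .aromatic_ok
      symbol <- if (aromatic) {
        paste0(toupper(substr(raw_sym, 1, 1)), substr(raw_sym, 2, nchar(raw_sym)))
      } else raw_sym
      chirality <- if (parts[3] == "@") "tet_ccw"
                   else if (parts[3] == "@@") "tet_cw" else "unspecified"
      n_h <- if (parts[4] == "") 0L
             else if (parts[5] == "") 1L else as.integer(parts[5])
      charge <- if (parts[6] == "") 0L else {
        cs <- parts[6]
        if (grepl("^[+-][0-9]+$", cs)) as.integer(cs)
        else as.integer(nchar(cs)) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
      }
      map <- if (parts[8] == "") 0L else as.integer(parts[8])
      idx <- add_atom(symbol, aromatic, charge, n_h, chirality, map, TRUE)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      pending <- NA_character_; prev <- idx
    } else if (grepl("[A-Za-z]", ch)) {
      two <- paste0(ch, peek(1L))
      symbol <- NA_character_; aromatic <- FALSE
      if (two %in% c("Cl", "Br")) {
        symbol <- two; pos <- pos + 2L
      } else if (ch %in% .organic_subset) {
        symbol <- ch; pos <- pos + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        symbol <- toupper(ch); aromatic <- TRUE; pos <- pos + 1L
      } else {
        stop("unexpected token '", ch, "' at position ", pos,
             " of SMILES '", s, "'", call. = FALSE)
      }
      idx <- add_atom(symbol, aromatic, 0L, 0L, "unspecified", 0L, FALSE)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      pending <- NA_character_; prev <- idx
    } else {
      stop("unexpected character '", ch, "' at position ", pos,
           " of SMILES '", s, "'", call. = FALSE)
    }
  }
  open_rings <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open_rings))
    stop("unclosed ring bond(s) ", paste(open_rings, collapse = ", "),
         " in SMILES '", s, "'", call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in SMILES '", s, "'", call. = FALSE)
  if (!length(sym)) stop("SMILES '", s, "' contains no atoms", call. = FALSE)

  # implicit hydrogen filling for bare organic-subset atoms
  bond_sum <- numeric(length(sym))
  if (length(bi)) {
    for (k in seq_along(bi)) {
      o <- .bond_order_num[[bord[k]]]
      bond_sum[bi[k]] <- bond_sum[bi[k]] + o
      bond_sum[bj[k]] <- bond_sum[bj[k]] + o
    }
  }
  for (a in seq_along(sym)) {
    if (!has_bracket_h[a]) {
      nh[a] <- .implicit_h(sym[a], bond_sum[a], chg[a])
    }
  }
  molgraph(symbols = sym, bonds = data.frame(i = bi, j = bj, order = bord,
                                             stringsAsFactors = FALSE),
           charge = chg, n_h = nh, chirality = chir, map = mapno,
           aromatic = arom)
}

# bond symbol needed before `to`-atom token given bond order and aromaticity
.bond_char <- function(order, arom_i, arom_j) {
  switch(order,
         single = if (arom_i && arom_j) "-" else "",
         double = "=",
         triple = "#",
         aromatic = if (arom_i && arom_j) "" else ":")
}

.atom_token <- function(g, a, with_maps) {
  symbol <- g$atom_symbols[a]
  arom <- g$aromatic[a]
  map <- if (with_maps) g$map[a] else 0L
  bond_sum <- g$valence[a] - g$n_h[a]
  plain_h <- .implicit_h(symbol, bond_sum, g$charge[a])
  needs_bracket <- map > 0L || g$charge[a] != 0L ||
    g$chirality[a] != "unspecified" ||
    !(symbol %in% .organic_subset) || g$n_h[a] != plain_h
  body <- if (arom) tolower(symbol) else symbol
  if (!needs_bracket) return(body)
  if (g$chirality[a] == "tet_ccw") body <- paste0(body, "@")
  if (g$chirality[a] == "tet_cw") body <- paste0(body, "@@")
  if (g$n_h[a] == 1L) body <- paste0(body, "H")
  if (g$n_h[a] > 1L) body <- paste0(body, "H", g$n_h[a])
  if (g$charge[a] != 0L) {
    sgn <- if (g$charge[a] > 0L) "+" else "-"
    k <- abs(g$charge[a])
    body <- paste0(body, if (k == 1L) sgn else paste0(sgn, k))
  }
  if (map > 0L) body <- paste0(body, ":", map)
  paste0("[", body, "]")
}

#' Write a molecular graph as a SMILES string
#'
#' Atoms are visited depth-first starting from the lowest atom index of
#' each connected component, so the output atom order is reproducible.
#' Components are joined with `.`.
#'
#' @param graph a [molgraph]
#' @param with_maps emit atom-map numbers stored in the graph (`:n`)
#' @return a SMILES string
#' @examples
#' write_smiles(parse_smiles("CC(=O)O"))
#' @export
write_smiles <- function(graph, with_maps = FALSE) {
  g <- graph
  n <- g$atom_count
  adj_list <- lapply(seq_len(n), function(i) which(g$adjacency[i, ] > 0))
  border <- matrix("", n, n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    border[i, j] <- border[j, i] <- g$bonds$order[k]
  }
  visited <- logical(n)
  ring_digit <- 0L
  ring_at <- vector("list", n)  # atom -> list of c(label, order-string, partner)

  out_component <- function(root) {
    # recursive DFS (neighbors in index order) so that the emitted atom
    # order equals the visit order; back edges become ring-closure bonds
    parent <- rep(NA_integer_, n)
    seen <- logical(n)
    children <- vector("list", n)
    back_edges <- list()
    dfs <- function(v) {
      seen[v] <<- TRUE
      for (w in adj_list[[v]]) {
        if (!seen[w]) {
          parent[w] <<- v
          children[[v]] <<- c(children[[v]], w)
          dfs(w)
        } else if (!identical(parent[v], w)) {
          key <- paste(min(v, w), max(v, w))
          back_edges[[key]] <<- c(min(v, w), max(v, w))
        }
      }
    }
    dfs(root)
    visited[seen] <<- TRUE
    for (e in back_edges) {
      ring_digit <<- ring_digit + 1L
      lab <- if (ring_digit <= 9L) as.character(ring_digit)
             else paste0("%", ring_digit)
      v <- e[1]; w <- e[2]
      ring_at[[v]] <<- c(ring_at[[v]], list(list(lab = lab, other = w)))
      ring_at[[w]] <<- c(ring_at[[w]], list(list(lab = lab, other = v)))
    }
    emit <- function(v, from) {
      tok <- .atom_token(g, v, with_maps)
      if (!is.na(from)) tok <- paste0(.bond_char(border[from, v],
                                                 g$aromatic[from],
                                                 g$aromatic[v]), tok)
      for (r in ring_at[[v]]) {
        tok <- paste0(tok, .bond_char(border[v, r$other],
                                      g$aromatic[v], g$aromatic[r$other]),
                      r$lab)
      }
      kids <- children[[v]]
      if (length(kids)) {
        pre <- if (length(kids) > 1L)
          paste0(vapply(kids[-length(kids)],
                        function(w) paste0("(", emit(w, v), ")"), ""),
                 collapse = "") else ""
        tok <- paste0(tok, pre, emit(kids[length(kids)], v))
      }
      tok
    }
    emit(root, NA_integer_)
  }

  parts <- character(0)
  repeat {
    root <- which(!visited)[1]
    if (is.na(root)) break
    parts <- c(parts, out_component(root))
  }
  paste(parts, collapse = ".")
}

#' Parse a reaction SMILES string
#'
#' Accepts `reactants>>products` (a middle agents field, if present, must
#' be empty: reagents and catalysts are outside the balanced-reaction
#' model).
#'
#' @param rxn_smiles reaction SMILES string
#' @return list with `reactants` and `products`, both [molgraph]s
#' @export
parse_reaction_smiles <- function(rxn_smiles) {
  fields <- strsplit(rxn_smiles, ">", fixed = TRUE)[[1]]
  if (length(fields) != 3L)
    stop("reaction SMILES must have the form reactants>>products: '",
         rxn_smiles, "'", call. = FALSE)
  if (nzchar(trimws(fields[2])))
    stop("agent field in reaction SMILES is not supported (reactions must ",
         "be balanced): '", rxn_smiles, "'", call. = FALSE)
  list(reactants = parse_smiles(fields[1]),
       products = parse_smiles(fields[3]))
}
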