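# Internal molecular-graph representation parsed from canonical SMILES.
#
# Molecules enter the package through OpenBabel canonicalization (see
# canonical_smiles()), so this parser only needs to understand the canonical
# dialect OpenBabel emits: organic-subset atoms, bracket atoms with isotope /
# chirality / H-count / charge, bond symbols - = # : / \, branches, ring
# closures (including %nn) and dot-separated fragments. Directional bonds
# (/ \) are read as single bonds: cis/trans geometry does not enter the
# circular-environment invariants.

.ELEMENT_Z <- c(
  H = 1, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
  Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
  Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29,
  Zn = 30, As = 33, Se = 34, Br = 35, Rb = 37, Sr = 38, Mo = 42, Pd = 46,
  Ag = 47, Cd = 48, Sn = 50, Sb = 51, I = 53, Cs = 55, Ba = 56, W = 74,
  Pt = 78, Au = 79, Hg = 80, Pb = 82, Bi = 83
)

# Standard valence alternatives for implicit-hydrogen completion of
# organic-subset atoms (Daylight convention: lowest valence >= bond sum).
.ORGANIC_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' @noRd
parse_smiles_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(element, aromatic, charge, hcount, chiral, bracket)
  bonds <- list()   # each: list(a1, a2, code) ; code in {"1","2","3","ar"} or NA (default)
  stack <- integer()
  prev <- NA_integer_
  pending <- NA_character_
  ring_open <- list()  # key = ring number, value = list(atom, code)

  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_,
                       chiral = 0L, bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = as.integer(charge),
      hcount = hcount, chiral = as.integer(chiral), bracket = bracket
    )
    length(atoms)
  }
  add_bond <- function(a1, a2, code) {
    if (is.na(code)) {
      code <- if (atoms[[a1]]$aromatic && atoms[[a2]]$aromatic) "ar" else "1"
    }
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, code = code)
  }
  connect <- function(idx) {
    force(idx)  # idx appends the atom; must happen before bonds read `atoms`
    if (!is.na(prev)) add_bond(prev, idx, pending)
    prev <<- idx
    pending <<- NA_character_
  }
  ring_bond <- function(num) {
    key <- as.character(num)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, code = pending)
      pending <<- NA_character_
    } else {
      open <- ring_open[[key]]
      code <- if (!is.na(pending)) pending else open$code
      add_bond(open$atom, prev, code)
      ring_open[[key]] <<- NULL
      pending <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles, call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regexec(
        "^([0-9]+)?([A-Za-z][a-z]?|\\*)(@@|@)?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
        body
      )
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0L)
        stop("unparsable bracket atom [", body, "] in SMILES: ", smiles, call. = FALSE)
      sym <- parts[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      element <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      if (!(element %in% names(.ELEMENT_Z)) && element != "*")
        stop("unknown element '", element, "' in SMILES: ", smiles,
             call. = FALSE)
      chiral <- switch(parts[4], "@" = 1L, "@@" = 2L, 0L)
      hc <- parts[5]
      hcount <- if (hc == "") 0L else if (hc == "H") 1L else as.integer(substring(hc, 2))
      chg <- parts[6]
      charge <- if (chg == "") 0L
        else if (chg %in% c("+", "-")) ifelse(chg == "+", 1L, -1L)
        else if (grepl("^[+-][0-9]+$", chg)) as.integer(chg)
        else (nchar(chg)) * ifelse(substr(chg, 1, 1) == "+", 1L, -1L)
      connect(add_atom(element, aromatic, charge, hcount, chiral, bracket = TRUE))
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        connect(add_atom(two, FALSE))
        i <- i + 2L
      } else {
        connect(add_atom(ch, FALSE))
        i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      connect(add_atom(toupper(ch), TRUE))
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- "1"; i <- i + 1L
    } else if (ch == "=") {
      pending <- "2"; i <- i + 1L
    } else if (ch == "#") {
      pending <- "3"; i <- i + 1L
    } else if (ch == ":") {
      pending <- "ar"; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stop("unbalanced parenthesis in SMILES: ", smiles, call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      ring_bond(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in SMILES: ", smiles, call. = FALSE)
      ring_bond(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_character_; i <- i + 1L
    } else {
      stop("unsupported SMILES character '", ch, "' in: ", smiles, call. = FALSE)
    }
  }
  if (length(ring_open) > 0L)
    stop("unmatched ring bond in SMILES: ", smiles, call. = FALSE)
  if (length(stack) > 0L)
    stop("unbalanced parenthesis in SMILES: ", smiles, call. = FALSE)
  if (length(atoms) == 0L)
    stop("SMILES contains no atoms: ", smiles, call. = FALSE)

  element <- vapply(atoms, `[[`, "", "element")
  aromatic <- vapply(atoms, `[[`, TRUE, "aromatic")
  charge <- vapply(atoms, `[[`, 0L, "charge")
  hcount <- vapply(atoms, `[[`, 0L, "hcount")
  chiral <- vapply(atoms, `[[`, 0L, "chiral")
  bracket <- vapply(atoms, `[[`, TRUE, "bracket")

  if (length(bonds) > 0L) {
    b1 <- vapply(bonds, `[[`, 0L, "a1")
    b2 <- vapply(bonds, `[[`, 0L, "a2")
    bcode <- vapply(bonds, `[[`, "", "code")
  } else {
    b1 <- integer(); b2 <- integer(); bcode <- character()
  }
  border <- ifelse(bcode == "ar", 1.5, as.numeric(ifelse(bcode == "ar", "1", bcode)))

  # implicit hydrogens for organic-subset (non-bracket) atoms
  bondsum <- numeric(length(atoms))
  for (k in seq_along(b1)) {
    bondsum[b1[k]] <- bondsum[b1[k]] + border[k]
    bondsum[b2[k]] <- bondsum[b2[k]] + border[k]
  }
  for (a in seq_along(atoms)) {
    if (!bracket[a]) {
      vals <- .ORGANIC_VALENCE[[element[a]]]
      if (is.null(vals)) {
        hcount[a] <- 0L
      } else {
        v <- vals[vals >= bondsum[a] - 1e-9]
        v <- if (length(v)) min(v) else max(vals)
        hcount[a] <- max(0L, as.integer(floor(v - bondsum[a] + 1e-9)))
      }
    }
  }

  z <- unname(.ELEMENT_Z[element])
  z[is.na(z)] <- 0L

  ring_atom <- rep(FALSE, length(atoms))
  if (length(b1) > 0L) {
    in_ring <- .bonds_in_rings(length(atoms), b1, b2)
    ring_atom[unique(c(b1[in_ring], b2[in_ring]))] <- TRUE
  } else {
    in_ring <- logical(0)
  }

  list(
    n_atoms = length(atoms),
    atoms = data.frame(
      element = element, z = z, aromatic = aromatic, charge = charge,
      hcount = hcount, chiral = chiral, in_ring = ring_atom,
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(a1 = b1, a2 = b2, order = border, in_ring = in_ring),
    smiles = smiles
  )
}

# A bond lies in a ring iff its endpoints stay connected after removing it.
#' @noRd
.bonds_in_rings <- function(n_atoms, b1, b2) {
  vapply(seq_along(b1), function(k) {
    keep <- setdiff(seq_along(b1), k)
    reach <- rep(FALSE, n_atoms)
    reach[b1[k]] <- TRUE
    frontier <- b1[k]
    while (length(frontier) > 0L) {
      nxt <- integer()
      for (e in keep) {
        if (reach[b1[e]] && !reach[b2[e]]) nxt <- c(nxt, b2[e])
        if (reach[b2[e]] && !reach[b1[e]]) nxt <- c(nxt, b1[e])
      }
      nxt <- unique(nxt)
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    reach[b2[k]]
  }, TRUE)
}

# Neighbor list: for each atom, data.frame(nbr, order, bond) of incident bonds.
#' @noRd
graph_adjacency <- function(g) {
  adj <- vector("list", g$n_atoms)
  for (a in seq_len(g$n_atoms)) adj[[a]] <- list(nbr = integer(), order = numeric(), bond = integer())
  bs <- g$bonds
  for (k in seq_len(nrow(bs))) {
    a1 <- bs$a1[k]; a2 <- bs$a2[k]; o <- bs$order[k]
    adj[[a1]]$nbr <- c(adj[[a1]]$nbr, a2)
    adj[[a1]]$order <- c(adj[[a1]]$order, o)
    adj[[a1]]$bond <- c(adj[[a1]]$bond, k)
    adj[[a2]]$nbr <- c(adj[[a2]]$nbr, a1)
    adj[[a2]]$order <- c(adj[[a2]]$order, o)
    adj[[a2]]$bond <- c(adj[[a2]]$bond, k)
  }
  adj
}

# Non-canonical SMILES for a connected bond-induced fragment, used to
# serialize fingerprint substructures. Aromatic atoms are written lowercase;
# the output is descriptive, not guaranteed round-trippable through an
# aromaticity model.
#' @noRd
fragment_smiles <- function(g, bond_ids, root) {
  if (length(bond_ids) == 0L) {
    return(.fragment_atom_token(g, root))
  }
  bs <- g$bonds[bond_ids, , drop = FALSE]
  atoms_in <- sort(unique(c(bs$a1, bs$a2, root)))
  adj <- lapply(seq_len(g$n_atoms), function(a) list(nbr = integer(), order = numeric()))
  for (k in seq_len(nrow(bs))) {
    a1 <- bs$a1[k]; a2 <- bs$a2[k]; o <- bs$order[k]
    adj[[a1]]$nbr <- c(adj[[a1]]$nbr, a2); adj[[a1]]$order <- c(adj[[a1]]$order, o)
    adj[[a2]]$nbr <- c(adj[[a2]]$nbr, a1); adj[[a2]]$order <- c(adj[[a2]]$order, o)
  }
  visited <- rep(FALSE, g$n_atoms)
  ring_counter <- 0L
  ring_labels <- character(g$n_atoms)  # pending closure digits per atom

  bond_sym <- function(o, a1, a2) {
    if (o == 2) "=" else if (o == 3) "#"
    else if (o == 1.5 && !(g$atoms$aromatic[a1] && g$atoms$aromatic[a2])) ":"
    else ""
  }

  # first pass marks back-edges (DFS on the fragment)
  visit_order <- integer()
  parent <- rep(NA_integer_, g$n_atoms)
  back_edges <- list()
  dfs <- function(a) {
    visited[a] <<- TRUE
    visit_order <<- c(visit_order, a)
    nb <- adj[[a]]
    for (j in seq_along(nb$nbr)) {
      b <- nb$nbr[j]
      if (!visited[b]) {
        parent[b] <<- a
        dfs(b)
      } else if (!identical(parent[a], b)) {
        key <- paste(sort(c(a, b)), collapse = "-")
        if (!key %in% names(back_edges)) back_edges[[key]] <<- c(a, b, nb$order[j])
      }
    }
  }
  dfs(root)

  ring_digit <- new.env(parent = emptyenv())
  for (key in names(back_edges)) {
    ring_counter <- ring_counter + 1L
    e <- back_edges[[key]]
    for (a in e[1:2]) {
      ring_labels[a] <- paste0(ring_labels[a], bond_sym(e[3], e[1], e[2]), ring_counter)
    }
  }

  visited2 <- rep(FALSE, g$n_atoms)
  emit <- function(a) {
    visited2[a] <<- TRUE
    out <- paste0(.fragment_atom_token(g, a), ring_labels[a])
    nb <- adj[[a]]
    kids <- which(!visited2[nb$nbr] & !is.na(parent[nb$nbr]) & parent[nb$nbr] == a)
    kids <- kids[!duplicated(nb$nbr[kids])]
    if (length(kids) > 0L) {
      parts <- vapply(seq_along(kids), function(i) {
        j <- kids[i]
        b <- nb$nbr[j]
        piece <- paste0(bond_sym(nb$order[j], a, b), emit(b))
        if (i < length(kids)) paste0("(", piece, ")") else piece
      }, "")
      out <- paste0(out, paste(parts, collapse = ""))
    }
    out
  }
  emit(root)
}

#' @noRd
.fragment_atom_token <- function(g, a) {
  el <- g$atoms$element[a]
  tok <- if (g$atoms$aromatic[a]) tolower(el) else el
  chg <- g$atoms$charge[a]
  if (chg != 0L) {
    sign <- if (chg > 0) "+" else "-"
    mag <- if (abs(chg) > 1L) abs(chg) else ""
    tok <- paste0("[", tok, sign, mag, "]")
  } else if (g$atoms$aromatic[a] && el == "N" && g$atoms$hcount[a] > 0L) {
    tok <- "[nH]"
  }
  tok
}
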