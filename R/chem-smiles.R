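# Molecular graph utilities on top of Open Babel (via ChemmineOB).
#
# All structure handling in the package funnels through this file: batch
# SMILES canonicalization, SMILES -> molecular graph, fragment graph ->
# MOL block -> canonical SMILES. Attachment points are encoded as dummy
# atoms ("*"); isotope labels on dummies ([1*], [2*]) distinguish the
# original substitution site from a second-round cut site in meta-cores.

# Batch conversion through Open Babel. `text` is a full multi-record
# payload (newline-separated SMILES or $$$$-separated MOL blocks).
ob_convert <- function(from, to, text) {
  if (!nzchar(text)) return(character(0))
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  strsplit(out, "\n", fixed = TRUE)[[1]]
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical form in one batched call.
#' Strings that fail to parse are returned as `NA` with a warning; the
#' result is positionally aligned with the input.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' \dontrun{
#' canonical_smiles(c("C1=CC=CC=C1C", "Cc1ccccc1"))  # both "Cc1ccccc1"
#' }
#' @export
canonical_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  payload <- paste0(smiles[idx], " t", idx, collapse = "\n")
  lines <- ob_convert("SMI", "CAN", paste0(payload, "\n"))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) == 2L && grepl("^t[0-9]+$", p[2L])) {
        out[as.integer(sub("^t", "", p[2L]))] <- p[1L]
      }
    }
  }
  # a hard parse error can abort the rest of an Open Babel batch; retry
  # the missing entries one at a time so later molecules are not lost
  for (i in which(ok & is.na(out))) {
    lines_i <- tryCatch(
      ob_convert("SMI", "CAN", paste0(smiles[i], " t1\n")),
      error = function(e) character(0)
    )
    if (length(lines_i) == 1L) {
      p <- strsplit(lines_i, "\t", fixed = TRUE)[[1]]
      if (length(p) == 2L && p[2L] == "t1") out[i] <- p[1L]
    }
  }
  failed <- which(ok & is.na(out))
  if (length(failed)) {
    cli::cli_warn("Failed to parse {length(failed)} SMILES string{?s} (position{?s} {.val {failed}}).")
  }
  out
}

# Parse V2000 MOL blocks (as emitted by Open Babel) into molecular graphs.
# Returns a named list (by title line) of lists with elements
#   atoms: tibble(elem, chg, iso)   bonds: tibble(a, b, order)
parse_molblocks <- function(lines) {
  recs <- split(lines, cumsum(c(TRUE, utils::head(lines, -1) == "$$$$")))
  res <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4L) next
    title <- rec[1L]
    counts <- rec[4L]
    na <- as.integer(substr(counts, 1L, 3L))
    nb <- as.integer(substr(counts, 4L, 6L))
    if (is.na(na) || is.na(nb)) next
    at <- rec[4L + seq_len(na)]
    elem <- trimws(substr(at, 32L, 34L))
    chg <- integer(na)
    iso <- integer(na)
    if (nb > 0L) {
      bl <- rec[4L + na + seq_len(nb)]
      bonds <- tibble::tibble(
        a = as.integer(substr(bl, 1L, 3L)),
        b = as.integer(substr(bl, 4L, 6L)),
        order = as.integer(substr(bl, 7L, 9L))
      )
    } else {
      bonds <- tibble::tibble(a = integer(0), b = integer(0), order = integer(0))
    }
    for (pl in rec[-seq_len(4L + na + nb)]) {
      tag <- substr(pl, 1L, 6L)
      if (tag %in% c("M  CHG", "M  ISO")) {
        n <- as.integer(substr(pl, 7L, 9L))
        for (k in seq_len(n)) {
          off <- 9L + (k - 1L) * 8L
          ai <- as.integer(substr(pl, off + 1L, off + 4L))
          vv <- as.integer(substr(pl, off + 5L, off + 8L))
          if (tag == "M  CHG") chg[ai] <- vv else iso[ai] <- vv
        }
      }
    }
    res[[title]] <- list(
      atoms = tibble::tibble(elem = elem, chg = chg, iso = iso),
      bonds = bonds
    )
  }
  res
}

# SMILES -> molecular graphs, batched. `smiles` must already be valid
# (canonicalize first); names are used as graph names. Explicit hydrogens,
# if any survive canonicalization, are removed so that atom counts are
# heavy-atom counts (dummy atoms "*" are kept but never counted as heavy).
mol_graphs <- function(smiles) {
  if (!length(smiles)) return(list())
  nm <- names(smiles)
  if (is.null(nm)) nm <- paste0("g", seq_along(smiles))
  payload <- paste0(smiles, " ", nm, collapse = "\n")
  lines <- ob_convert("SMI", "SDF", paste0(payload, "\n"))
  graphs <- parse_molblocks(lines)
  lapply(graphs, drop_explicit_h)
}

drop_explicit_h <- function(g) {
  h <- which(g$atoms$elem == "H")
  if (!length(h)) return(g)
  keep <- setdiff(seq_len(nrow(g$atoms)), h)
  remap <- match(seq_len(nrow(g$atoms)), keep)
  bonds <- g$bonds[!(g$bonds$a %in% h | g$bonds$b %in% h), , drop = FALSE]
  bonds$a <- remap[bonds$a]
  bonds$b <- remap[bonds$b]
  list(atoms = g$atoms[keep, , drop = FALSE], bonds = bonds)
}

heavy_atoms <- function(g) which(!(g$atoms$elem %in% c("H", "*")))

# Serialize a graph (atoms/bonds tibbles) to a V2000 MOL block string.
graph_to_molblock <- function(g, title) {
  na <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  hdr <- c(title, "  acnet", "", sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  al <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    g$atoms$elem
  )
  bl <- if (nb) sprintf("%3d%3d%3d  0  0  0  0", g$bonds$a, g$bonds$b, g$bonds$order) else character(0)
  prop <- character(0)
  chg <- which(g$atoms$chg != 0L)
  if (length(chg)) {
    prop <- c(prop, sprintf(
      "M  CHG%3d%s", length(chg),
      paste0(sprintf("%4d%4d", chg, g$atoms$chg[chg]), collapse = "")
    ))
  }
  iso <- which(g$atoms$iso != 0L)
  if (length(iso)) {
    prop <- c(prop, sprintf(
      "M  ISO%3d%s", length(iso),
      paste0(sprintf("%4d%4d", iso, g$atoms$iso[iso]), collapse = "")
    ))
  }
  paste(c(hdr, al, bl, prop, "M  END", "$$$$"), collapse = "\n")
}

# Named list of graphs -> canonical SMILES (batched). Unparseable records
# come back NA.
graphs_to_smiles <- function(graphs) {
  if (!length(graphs)) return(character(0))
  nm <- paste0("t", seq_along(graphs))
  blocks <- vapply(seq_along(graphs), function(i) {
    graph_to_molblock(graphs[[i]], nm[i])
  }, character(1))
  lines <- ob_convert("SDF", "CAN", paste(blocks, collapse = "\n"))
  out <- rep(NA_character_, length(graphs))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) == 2L && grepl("^t[0-9]+$", p[2L])) {
        out[as.integer(sub("^t", "", p[2L]))] <- p[1L]
      }
    }
  }
  names(out) <- names(graphs)
  out
}

# Extract the induced subgraph on `keep` atom indices, optionally adding a
# dummy atom ("*", isotope `mark_iso`) bonded to `attach` (an atom index in
# the parent numbering). Used to write cut fragments.
subgraph_with_mark <- function(g, keep, attach = NA_integer_, mark_iso = 0L) {
  keep <- sort(keep)
  remap <- match(seq_len(nrow(g$atoms)), keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  bonds <- g$bonds[!is.na(remap[g$bonds$a]) & !is.na(remap[g$bonds$b]), , drop = FALSE]
  bonds$a <- remap[bonds$a]
  bonds$b <- remap[bonds$b]
  if (!is.na(attach)) {
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(elem = "*", chg = 0L, iso = as.integer(mark_iso)))
    bonds <- dplyr::bind_rows(bonds, tibble::tibble(a = remap[attach], b = nrow(atoms), order = 1L))
  }
  list(atoms = atoms, bonds = bonds)
}

#' Reattach a substituent to a marked core
#'
#' Joins a core and a substituent, each carrying a single dummy-atom
#' attachment marker (`*`), by bonding the two marked positions. The
#' result reproduces the parent compound of a fragmentation record.
#'
#' @param core_key Canonical SMILES of a core with one `*` marker.
#' @param substituent_key Canonical SMILES of a substituent with one `*` marker.
#' @return Canonical SMILES of the reassembled molecule.
#' @export
attach_substituent <- function(core_key, substituent_key) {
  stopifnot(length(core_key) == length(substituent_key))
  pieces <- mol_graphs(stats::setNames(
    c(core_key, substituent_key),
    c(paste0("c", seq_along(core_key)), paste0("s", seq_along(core_key)))
  ))
  merged <- vector("list", length(core_key))
  for (i in seq_along(core_key)) {
    gc <- pieces[[paste0("c", i)]]
    gs <- pieces[[paste0("s", i)]]
    if (!is.null(gc) && !is.null(gs)) {
      m <- merge_at_markers(gc, gs)
      if (is.list(m)) merged[[i]] <- m
    }
  }
  res <- rep(NA_character_, length(core_key))
  ok <- which(!vapply(merged, is.null, logical(1)))
  if (length(ok)) res[ok] <- graphs_to_smiles(merged[ok])
  res
}

# Merge two graphs each containing exactly one "*" marker: remove both
# markers and bond their neighbours. Returns a graph, or NA on bad input.
merge_at_markers <- function(ga, gb) {
  star_a <- which(ga$atoms$elem == "*")
  star_b <- which(gb$atoms$elem == "*")
  if (length(star_a) != 1L || length(star_b) != 1L) return(NA)
  nb_a <- neighbour_of(ga, star_a)
  nb_b <- neighbour_of(gb, star_b)
  keep_a <- setdiff(seq_len(nrow(ga$atoms)), star_a)
  keep_b <- setdiff(seq_len(nrow(gb$atoms)), star_b)
  sa <- subgraph_with_mark(ga, keep_a)
  sb <- subgraph_with_mark(gb, keep_b)
  off <- nrow(sa$atoms)
  bonds_b <- sb$bonds
  bonds_b$a <- bonds_b$a + off
  bonds_b$b <- bonds_b$b + off
  atoms <- dplyr::bind_rows(sa$atoms, sb$atoms)
  join <- tibble::tibble(
    a = match(nb_a, keep_a),
    b = match(nb_b, keep_b) + off,
    order = 1L
  )
  list(atoms = atoms, bonds = dplyr::bind_rows(sa$bonds, bonds_b, join))
}

neighbour_of <- function(g, i) {
  c(g$bonds$b[g$bonds$a == i], g$bonds$a[g$bonds$b == i])[1L]
}

# Heavy-atom count per SMILES (batched; NA for unparseable input).
smiles_heavy_count <- function(smiles) {
  graphs <- mol_graphs(stats::setNames(smiles, paste0("h", seq_along(smiles))))
  out <- rep(NA_integer_, length(smiles))
  hit <- match(paste0("h", seq_along(smiles)), names(graphs))
  found <- which(!is.na(hit))
  out[found] <- vapply(graphs[hit[found]], function(g) length(heavy_atoms(g)), integer(1))
  out
}

# Keep the largest covalent component of each SMILES (desalting). Input
# need not be canonical; output is canonical. NA stays NA.
desalt_smiles <- function(smiles) {
  can <- canonical_smiles(smiles)
  multi <- which(!is.na(can) & grepl(".", can, fixed = TRUE))
  for (i in multi) {
    parts <- strsplit(can[i], ".", fixed = TRUE)[[1]]
    hv <- smiles_heavy_count(parts)
    best <- parts[which.max(hv)]
    can[i] <- canonical_smiles(best)
  }
  can
}
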