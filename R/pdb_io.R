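#' Read a multi-model PDB file as a trajectory
#'
#' Parses standard `ATOM`/`HETATM`/`MODEL`/`ENDMDL` records. Each `MODEL`
#' block becomes one frame; a file without `MODEL` records yields a
#' single-frame trajectory. The topology is taken from the first model
#' (author residue numbering, element from columns 77-78 with a fallback
#' inferred from the atom name); every later model must present the same
#' atom set in the same order. `HETATM` atoms are kept in a separate ligand
#' partition. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties: first encountered). Only single-chain
#' protein input is accepted, so residue identity collapses to the author
#' residue number.
#'
#' @param path path to a PDB file.
#' @param frame_interval_ps sampling interval metadata attached to the
#'   result.
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path, frame_interval_ps = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0L) stop("no ATOM/HETATM records in ", path,
                                     call. = FALSE)
  models <- split(atom_lines, model_of[atom_lines])
  parsed <- lapply(models, parse_pdb_atoms, lines = lines)
  topo_keys <- lapply(parsed, function(p)
    paste(p$name, p$residue_number, p$residue_name, p$is_ligand))
  first <- parsed[[1L]]
  for (m in seq_along(parsed)[-1L]) {
    if (!identical(topo_keys[[m]], topo_keys[[1L]])) {
      stop("topology mismatch: model ", m, " does not present the atom set ",
           "of model 1", call. = FALSE)
    }
  }
  chains <- unique(first$chain[!first$is_ligand])
  chains <- chains[chains != ""]
  if (length(chains) > 1L) {
    stop("multi-chain protein input not supported (chains: ",
         paste(chains, collapse = ", "), ")", call. = FALSE)
  }
  topo <- make_topology(first$serial, first$name, first$element,
                        first$residue_number, first$residue_name,
                        is_ligand = first$is_ligand)
  coords <- array(NA_real_, c(nrow(topo), 3L, length(parsed)))
  for (m in seq_along(parsed)) {
    coords[, , m] <- cbind(parsed[[m]]$x, parsed[[m]]$y, parsed[[m]]$z)
  }
  trajectory(topo, coords, frame_interval_ps)
}

parse_pdb_atoms <- function(idx, lines) {
  txt <- lines[idx]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(txt, from, to)))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1L]]
      stop("unparsable ", what, " in ATOM record at line ", bad,
           call. = FALSE)
    }
    v
  }
  p <- list(
    serial = as.integer(num(7L, 11L, "serial")),
    name = trimws(substr(txt, 13L, 16L)),
    altloc = substr(txt, 17L, 17L),
    residue_name = trimws(substr(txt, 18L, 20L)),
    chain = trimws(substr(txt, 22L, 22L)),
    residue_number = as.integer(num(23L, 26L, "residue number")),
    x = num(31L, 38L, "x coordinate"),
    y = num(39L, 46L, "y coordinate"),
    z = num(47L, 54L, "z coordinate"),
    occupancy = {
      o <- suppressWarnings(as.numeric(substr(txt, 55L, 60L)))
      ifelse(is.na(o), 1, o)
    },
    element = trimws(substr(txt, 77L, 78L)),
    is_ligand = substr(txt, 1L, 6L) == "HETATM"
  )
  blank <- p$element == ""
  if (any(blank)) p$element[blank] <- element_from_name(p$name[blank])
  p <- resolve_altloc(p)
  p
}

# Fallback element inference from the atom name: strip leading digits, take
# the leading letter(s); 4-character hydrogen names like "1HB2" map to H.
element_from_name <- function(name) {
  core <- sub("^[0-9']+", "", name)
  el <- toupper(substr(core, 1L, 1L))
  two <- toupper(substr(core, 1L, 2L))
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")]
  el
}

resolve_altloc <- function(p) {
  key <- paste(p$is_ligand, p$residue_number, p$name)
  if (!anyDuplicated(key)) return(p)
  keep <- rep(TRUE, length(key))
  for (k in unique(key[duplicated(key)])) {
    at <- which(key == k)
    best <- at[which.max(p$occupancy[at])]  # tie -> first encountered
    keep[setdiff(at, best)] <- FALSE
  }
  lapply(p, function(v) v[keep])
}

#' Write a trajectory or frame as a multi-model PDB file
#'
#' @param x a `Trajectory` or `StructureFrame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "StructureFrame")) {
    x <- trajectory(x$topology, array(x$coords, c(nrow(x$coords), 3L, 1L)))
  }
  stopifnot(inherits(x, "Trajectory"))
  topo <- x$topology
  J <- n_frames(x)
  con <- file(path, "w")
  on.exit(close(con))
  rec <- ifelse(topo$is_ligand, "HETATM", "ATOM  ")
  for (j in seq_len(J)) {
    if (J > 1L) writeLines(sprintf("MODEL     %4d", j), con)
    writeLines(sprintf(
      "%s%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, topo$atom_id, format_atom_name(topo$name), topo$residue_name,
      topo$residue_number, x$coords[, 1L, j], x$coords[, 2L, j],
      x$coords[, 3L, j], 1, 0, topo$element), con)
    if (J > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# PDB convention: 1-3 character names start in column 14.
format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4L, name, paste0(" ", name))
}
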