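FIXTURE_SCHEMA_VERSION <- 1L

#' Write a trajectory in the canonical fixture format
#'
#' The fixture format is a pair of plain-text files designed for
#' bit-stable golden tests: `<prefix>.json` holds the schema version, frame
#' interval and atom table, `<prefix>.csv` holds one row per atom per frame
#' (`frame_index, atom_id, x, y, z`) with coordinates printed at full
#' double precision (`%.17g`), so `read_fixture(write_fixture(T))`
#' reproduces `T` exactly.
#'
#' @param traj a [trajectory()].
#' @param prefix output path prefix; `.json` and `.csv` are appended.
#' @return `prefix`, invisibly.
#' @export
write_fixture <- function(traj, prefix) {
  stopifnot(inherits(traj, "Trajectory"))
  topo <- traj$topology
  meta <- list(
    schema_version = FIXTURE_SCHEMA_VERSION,
    frame_interval_ps = traj$frame_interval_ps,
    atoms = topo[, c("atom_id", "name", "element", "residue_number",
                     "residue_name", "is_ligand")]
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  J <- n_frames(traj)
  n <- nrow(topo)
  co <- matrix(aperm(traj$coords, c(1L, 3L, 2L)), n * J, 3L)
  df <- data.frame(
    frame_index = rep(seq_len(J), each = n),
    atom_id = rep(topo$atom_id, J),
    x = sprintf("%.17g", co[, 1L]),
    y = sprintf("%.17g", co[, 2L]),
    z = sprintf("%.17g", co[, 3L])
  )
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(prefix)
}

#' Read a trajectory from the canonical fixture format
#'
#' @param prefix path prefix as used by [write_fixture()].
#' @return A [trajectory()]; an exact round-trip of what was written.
#' @export
read_fixture <- function(prefix) {
  json_path <- paste0(prefix, ".json")
  csv_path <- paste0(prefix, ".csv")
  for (p in c(json_path, csv_path)) {
    if (!file.exists(p)) stop("fixture file not found: ", p, call. = FALSE)
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version)) {
    stop("fixture schema violation at /schema_version: missing",
         call. = FALSE)
  }
  if (meta$schema_version != FIXTURE_SCHEMA_VERSION) {
    stop("fixture schema violation at /schema_version: got ",
         meta$schema_version, ", expected ", FIXTURE_SCHEMA_VERSION,
         call. = FALSE)
  }
  atoms <- meta$atoms
  req <- c("atom_id", "name", "element", "residue_number", "residue_name")
  for (f in req) {
    if (is.null(atoms[[f]])) {
      stop("fixture schema violation at /atoms/", f, ": missing",
           call. = FALSE)
    }
  }
  if (is.null(atoms$is_ligand)) atoms$is_ligand <- FALSE
  topo <- make_topology(atoms$atom_id, atoms$name, atoms$element,
                        atoms$residue_number, atoms$residue_name,
                        is_ligand = atoms$is_ligand)
  tab <- utils::read.csv(csv_path, colClasses = c(
    frame_index = "integer", atom_id = "integer", x = "numeric",
    y = "numeric", z = "numeric"))
  if (nrow(tab) == 0L) {
    stop("fixture schema violation at /frames: empty coordinate table ",
         "(J >= 1 required)", call. = FALSE)
  }
  frames <- unique(tab$frame_index)
  if (!identical(frames, seq_along(frames))) {
    stop("fixture schema violation at /frames: frame_index must run 1..J",
         call. = FALSE)
  }
  n <- nrow(topo)
  J <- length(frames)
  if (nrow(tab) != n * J) {
    stop("fixture schema violation at /frames: expected ", n * J,
         " coordinate rows, found ", nrow(tab), call. = FALSE)
  }
  id_order <- match(tab$atom_id, topo$atom_id)
  if (anyNA(id_order)) {
    stop("fixture schema violation at /frames/atom_id: unknown atom id",
         call. = FALSE)
  }
  coords <- array(NA_real_, c(n, 3L, J))
  ax <- c("x", "y", "z")
  for (j in seq_len(J)) {
    rows <- which(tab$frame_index == j)
    if (!identical(sort(id_order[rows]), seq_len(n))) {
      stop("fixture schema violation at /frames: frame ", j,
           " does not cover the atom set exactly once", call. = FALSE)
    }
    for (a in 1:3) coords[id_order[rows], a, j] <- tab[[ax[a]]][rows]
  }
  if (!all(is.finite(coords))) {
    stop("fixture schema violation at /frames: non-finite coordinates",
         call. = FALSE)
  }
  trajectory(topo, coords, meta$frame_interval_ps)
}
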