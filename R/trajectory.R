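#' Trajectory frames with atom roles and an orthorhombic box
#'
#' A `traj_frames` object holds a list of per-frame coordinate matrices
#' (n_atoms x 3, Angstrom) plus shared per-atom labels: `element` and a
#' `role` tag used by the hydration analysis (`"copper"` for the RDF
#' reference, `"water_oxygen"` for targets; anything else is carried
#' along). The periodic box, if any, is orthorhombic and given as three
#' edge lengths in Angstrom. Triclinic boxes are rejected.
#'
#' @param coords List of n x 3 numeric matrices, one per frame.
#' @param element Character vector of element symbols, length n.
#' @param role Character vector of role tags, length n. Defaults map
#'   Cu -> copper, O -> water_oxygen, H -> water_hydrogen, else "other".
#' @param box `NULL` or numeric length-3 box edge lengths, Angstrom.
#' @return Object of class `traj_frames`.
#' @export
traj_frames <- function(coords, element, role = NULL, box = NULL) {
  if (!is.list(coords) || !length(coords)) stop("coords must be a non-empty list")
  n <- nrow(coords[[1]])
  for (m in coords) {
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n)
      stop("every frame must be an n x 3 matrix with constant n")
    if (!all(is.finite(m))) stop("non-finite coordinates")
  }
  if (length(element) != n) stop("element labels must match atom count")
  if (is.null(role)) role <- default_roles(element)
  if (length(role) != n) stop("role labels must match atom count")
  if (!is.null(box)) {
    if (is.matrix(box) || length(box) != 3L)
      stop("unsupported box format: only orthorhombic length-3 boxes are supported")
    if (!all(box > 0)) stop("box lengths must be > 0")
    box <- as.numeric(box)
  }
  structure(list(coords = coords, element = as.character(element),
                 role = as.character(role), box = box),
            class = "traj_frames")
}

#' @rdname traj_frames
#' @export
default_roles <- function(element) {
  r <- rep("other", length(element))
  r[toupper(element) == "CU"] <- "copper"
  r[toupper(element) == "O"] <- "water_oxygen"
  r[toupper(element) == "H"] <- "water_hydrogen"
  r
}

#' @export
print.traj_frames <- function(x, ...) {
  cat(sprintf("traj_frames: %d frames, %d atoms%s\n",
              length(x$coords), length(x$element),
              if (is.null(x$box)) "" else
                sprintf(", box %.2f x %.2f x %.2f A",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks (atom count, comment, `element x y z` lines)
#' repeated per frame. An optional JSON sidecar supplies the box and roles:
#' fields `box` (three lengths, Angstrom), and either `roles` (per-atom
#' array) or `role_map` (element symbol -> role).
#'
#' @param path XYZ file.
#' @param meta Optional path to the JSON sidecar.
#' @return A [traj_frames()] object.
#' @export
read_xyz_frames <- function(path, meta = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  element <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L) stop("malformed XYZ: bad atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("malformed XYZ: truncated frame")
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- matrix(as.numeric(vapply(parts, function(p) p[2:4], character(3))),
                  ncol = 3L, byrow = TRUE)
    if (is.null(element)) element <- el
    else if (!identical(el, element)) stop("atom order changes between frames")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  box <- NULL; role <- NULL
  if (!is.null(meta)) {
    md <- jsonlite::read_json(meta, simplifyVector = TRUE)
    if (!is.null(md$box)) box <- as.numeric(md$box)
    if (!is.null(md$roles)) role <- as.character(md$roles)
    else if (!is.null(md$role_map)) {
      rm_ <- unlist(md$role_map)
      role <- default_roles(element)
      hit <- element %in% names(rm_)
      role[hit] <- unname(rm_[element[hit]])
    }
  }
  traj_frames(frames, element, role = role, box = box)
}

#' Write a multi-frame XYZ trajectory (with optional JSON sidecar)
#'
#' @param traj A [traj_frames()] object.
#' @param path Output XYZ path.
#' @param meta Optional output path for the JSON sidecar (box + roles).
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(traj, path, meta = NULL) {
  stopifnot(inherits(traj, "traj_frames"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(traj$element)
  for (f in seq_along(traj$coords)) {
    writeLines(c(as.character(n), sprintf("frame %d", f)), con)
    xyz <- traj$coords[[f]]
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f",
                       traj$element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  if (!is.null(meta)) {
    jsonlite::write_json(
      list(box = traj$box, roles = traj$role), meta,
      auto_unbox = FALSE, digits = NA, null = "null")
  }
  invisible(path)
}
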