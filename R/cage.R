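#' Parameters of the parametric trussed PLIF cage
#'
#' The cage is represented as a regular box lattice of titanium struts: two
#' rectangular node grids (caudal and cranial contact surfaces) joined by
#' vertical struts and X-braced diagonals, with in-plane chords on each
#' surface. A posterior sub-lattice stands in for the solid screw-insertion
#' block: its struts get an enlarged effective diameter so the block behaves
#' as a stiff region while staying inside the beam formulation.
#'
#' Coordinates: x lateral (mirror-symmetric about the cage midsagittal plane
#' x = 0), y anterior-posterior (0 = posterior face, `length` = anterior
#' face), z caudal-cranial (0 = caudal surface).
#'
#' @param footprint_mm Numeric `c(length, width)` of the endplate footprint in
#'   mm (length runs anterior-posterior).
#' @param height_mm Cage height in mm.
#' @param strut_diameter_mm Nominal strut diameter in mm.
#' @param lattice_pitch_mm Target node spacing in mm; must not exceed either
#'   footprint dimension.
#' @param screw_block_fraction Posterior fraction of the cage length treated
#'   as the screw-insertion block, in `[0, 0.5]`.
#' @param block_diameter_factor Multiplier on strut diameter inside the screw
#'   block (default 3, i.e. ~81x bending stiffness).
#' @param material Named numeric `c(E_MPa, nu)`; defaults to Ti-6Al-4V
#'   (E = 116000 MPa, nu = 0.32).
#' @param jitter_mm Amplitude of seeded uniform node-coordinate jitter
#'   (default 0 = off; used to break symmetry in robustness studies).
#' @return An object of class `cage_params`.
#' @export
cage_params <- function(footprint_mm = c(25, 10), height_mm = 11,
                        strut_diameter_mm = 0.5, lattice_pitch_mm = 3,
                        screw_block_fraction = 0.20,
                        block_diameter_factor = 3,
                        material = c(E_MPa = 116000, nu = 0.32),
                        jitter_mm = 0) {
  if (length(footprint_mm) != 2L || any(footprint_mm <= 0))
    stop_arg("`footprint_mm` must be c(length, width), both > 0")
  check_number(height_mm, "height_mm", positive = TRUE)
  check_number(strut_diameter_mm, "strut_diameter_mm", positive = TRUE)
  check_number(lattice_pitch_mm, "lattice_pitch_mm", positive = TRUE)
  check_number(screw_block_fraction, "screw_block_fraction", nonneg = TRUE)
  if (screw_block_fraction > 0.5)
    stop_arg("`screw_block_fraction` must lie in [0, 0.5]")
  check_number(block_diameter_factor, "block_diameter_factor", positive = TRUE)
  check_number(jitter_mm, "jitter_mm", nonneg = TRUE)
  if (length(material) != 2L || material[[1]] <= 0)
    stop_arg("`material` must be c(E_MPa, nu) with E > 0")
  structure(list(footprint_mm = as.numeric(footprint_mm),
                 height_mm = height_mm,
                 strut_diameter_mm = strut_diameter_mm,
                 lattice_pitch_mm = lattice_pitch_mm,
                 screw_block_fraction = screw_block_fraction,
                 block_diameter_factor = block_diameter_factor,
                 material = c(E_MPa = as.numeric(material[[1]]),
                              nu = as.numeric(material[[2]])),
                 jitter_mm = jitter_mm),
            class = "cage_params")
}

#' Generate a trussed cage lattice
#'
#' Builds the node/strut graph of the parametric PLIF cage described by
#' [cage_params()]. With jitter disabled (the default) the node coordinates
#' are bilaterally mirror-symmetric about the cage midsagittal plane by
#' construction, and generation is fully deterministic; with `jitter_mm > 0`
#' a seeded uniform perturbation is added to every coordinate.
#'
#' @param params A [cage_params()] object.
#' @param seed Integer seed (only consumed when jitter is enabled).
#' @return An object of class `cage_lattice` with fields `nodes` (n x 3 mm),
#'   `struts` (data.frame `i`, `j`, `diameter_mm`), `sets` (named integer
#'   vectors `cranial_surface`, `caudal_surface`, `screw_block`), `material`,
#'   and `params`.
#' @examples
#' cage <- generate_cage(cage_params())
#' cage
#' @export
generate_cage <- function(params = cage_params(), seed = 1) {
  stopifnot(inherits(params, "cage_params"))
  L <- params$footprint_mm[1]; W <- params$footprint_mm[2]
  H <- params$height_mm; p <- params$lattice_pitch_mm
  ny <- floor(L / p) + 1L
  nx <- floor(W / p) + 1L
  if (ny < 2L || nx < 2L)
    stop_arg("lattice pitch exceeds the cage footprint: no interior nodes")
  ys <- seq(0, L, length.out = ny)
  xs <- seq(-W / 2, W / 2, length.out = nx)     # symmetric about x = 0
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  n_layer <- nrow(grid)
  nodes <- rbind(cbind(grid$x, grid$y, 0), cbind(grid$x, grid$y, H))
  bot <- function(ix, iy) (iy - 1L) * nx + ix            # caudal layer ids
  top <- function(ix, iy) n_layer + (iy - 1L) * nx + ix  # cranial layer ids

  ii <- integer(0); jj <- integer(0)
  add <- function(a, b) { ii <<- c(ii, a); jj <<- c(jj, b) }
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    add(bot(ix, iy), top(ix, iy))                        # verticals
    if (ix < nx) { add(bot(ix, iy), bot(ix + 1L, iy))    # chords along x
                   add(top(ix, iy), top(ix + 1L, iy)) }
    if (iy < ny) { add(bot(ix, iy), bot(ix, iy + 1L))    # chords along y
                   add(top(ix, iy), top(ix, iy + 1L)) }
    if (iy < ny) { add(bot(ix, iy), top(ix, iy + 1L))    # X-brace, y-bays
                   add(bot(ix, iy + 1L), top(ix, iy)) }
    if (ix < nx) { add(bot(ix, iy), top(ix + 1L, iy))    # X-brace, x-bays
                   add(bot(ix + 1L, iy), top(ix, iy)) }
  }

  if (params$jitter_mm > 0) {
    nodes <- nodes + with_seed(seed, matrix(
      stats::runif(length(nodes), -params$jitter_mm, params$jitter_mm),
      nrow(nodes), 3))
  }

  y_block <- params$screw_block_fraction * L
  in_block <- nodes[, 2] <= y_block + 1e-9
  diam <- rep(params$strut_diameter_mm, length(ii))
  diam[in_block[ii] & in_block[jj]] <-
    params$strut_diameter_mm * params$block_diameter_factor

  lat <- structure(list(
    nodes = nodes,
    struts = data.frame(i = ii, j = jj, diameter_mm = diam),
    sets = list(cranial_surface = seq.int(n_layer + 1L, 2L * n_layer),
                caudal_surface = seq_len(n_layer),
                screw_block = which(in_block)),
    material = params$material,
    params = params), class = "cage_lattice")
  validate_lattice(lat)
  lat
}

#' Validate a cage lattice
#'
#' Checks the structural invariants: non-empty disjoint contact surfaces,
#' strictly positive strut diameters, no zero-length struts, and a single
#' connected strut graph (breadth-first traversal).
#'
#' @param lattice A `cage_lattice`.
#' @return The lattice, invisibly; errors otherwise.
#' @export
validate_lattice <- function(lattice) {
  stopifnot(inherits(lattice, "cage_lattice"))
  n <- nrow(lattice$nodes); s <- lattice$struts
  if (!length(lattice$sets$cranial_surface) ||
      !length(lattice$sets$caudal_surface))
    stop_arg("contact surfaces must be non-empty")
  if (length(intersect(lattice$sets$cranial_surface,
                       lattice$sets$caudal_surface)))
    stop_arg("cranial and caudal surfaces must be disjoint")
  if (any(s$diameter_mm <= 0)) stop_arg("all strut diameters must be > 0")
  len <- sqrt(rowSums((lattice$nodes[s$i, , drop = FALSE] -
                       lattice$nodes[s$j, , drop = FALSE])^2))
  if (any(len < 1e-12)) stop_arg("zero-length strut detected")
  # connectivity by BFS over the adjacency list
  adj <- vector("list", n)
  for (k in seq_len(nrow(s))) {
    adj[[s$i[k]]] <- c(adj[[s$i[k]]], s$j[k])
    adj[[s$j[k]]] <- c(adj[[s$j[k]]], s$i[k])
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]; new <- nb[!seen[nb]]
    seen[new] <- TRUE; queue <- c(queue, new)
  }
  if (!all(seen)) stop_arg("strut graph is not a single connected component")
  invisible(lattice)
}

strut_lengths <- function(lattice) {
  s <- lattice$struts
  sqrt(rowSums((lattice$nodes[s$i, , drop = FALSE] -
                lattice$nodes[s$j, , drop = FALSE])^2))
}

#' @export
print.cage_lattice <- function(x, ...) {
  cat(sprintf("<cage_lattice> %d nodes, %d struts\n",
              nrow(x$nodes), nrow(x$struts)))
  cat(sprintf("  footprint %.1f x %.1f mm, height %.1f mm; strut d %.2f mm (block x%.1f)\n",
              x$params$footprint_mm[1], x$params$footprint_mm[2],
              x$params$height_mm, x$params$strut_diameter_mm,
              x$params$block_diameter_factor))
  cat(sprintf("  surface nodes: %d cranial / %d caudal; %d screw-block nodes\n",
              length(x$sets$cranial_surface), length(x$sets$caudal_surface),
              length(x$sets$screw_block)))
  cat(sprintf("  material: E = %.0f MPa, nu = %.2f; total strut surface %.1f mm^2\n",
              x$material[["E_MPa"]], x$material[["nu"]],
              sum(pi * x$struts$diameter_mm * strut_lengths(x))))
  invisible(x)
}

#' Write a lattice as a plain-text node/strut file
#'
#' Whitespace-delimited format: a `# nodes: id x y z` section followed by a
#' `# struts: id i j diameter` section.
#'
#' @param lattice A `cage_lattice`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lattice_txt <- function(lattice, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# nodes: id x y z", con)
  n <- nrow(lattice$nodes)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(n),
                     lattice$nodes[, 1], lattice$nodes[, 2],
                     lattice$nodes[, 3]), con)
  writeLines("# struts: id i j diameter", con)
  s <- lattice$struts
  writeLines(sprintf("%d %d %d %.10g", seq_len(nrow(s)), s$i, s$j,
                     s$diameter_mm), con)
  for (nm in names(lattice$sets))
    writeLines(paste("# set:", nm,
                     paste(lattice$sets[[nm]], collapse = " ")), con)
  writeLines(sprintf("# material: E_MPa %.10g nu %.10g",
                     lattice$material[["E_MPa"]], lattice$material[["nu"]]),
             con)
  invisible(path)
}

#' Read a lattice from the plain-text node/strut format
#'
#' @param path File written by [write_lattice_txt()] (or hand-authored in the
#'   same format; set lines and the material line are optional, in which case
#'   surfaces default to the lowest/highest z node layers and Ti-6Al-4V).
#' @return A `cage_lattice`.
#' @export
read_lattice_txt <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  section <- NA_character_; sets <- list()
  material <- c(E_MPa = 116000, nu = 0.32)
  node_rows <- list(); strut_rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      if (grepl("^#\\s*nodes", ln)) section <- "nodes"
      else if (grepl("^#\\s*struts", ln)) section <- "struts"
      else if (grepl("^#\\s*set:", ln)) {
        tok <- strsplit(sub("^#\\s*set:\\s*", "", ln), "\\s+")[[1]]
        sets[[tok[1]]] <- as.integer(tok[-1])
      } else if (grepl("^#\\s*material:", ln)) {
        tok <- strsplit(sub("^#\\s*material:\\s*", "", ln), "\\s+")[[1]]
        material <- c(E_MPa = as.numeric(tok[2]), nu = as.numeric(tok[4]))
      }
      next
    }
    tok <- as.numeric(strsplit(ln, "\\s+")[[1]])
    if (identical(section, "nodes")) node_rows[[length(node_rows) + 1L]] <- tok
    else if (identical(section, "struts"))
      strut_rows[[length(strut_rows) + 1L]] <- tok
  }
  if (!length(node_rows) || !length(strut_rows))
    stop_arg("lattice file must contain node and strut sections")
  nm <- do.call(rbind, node_rows); sm <- do.call(rbind, strut_rows)
  nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  struts <- data.frame(i = as.integer(sm[, 2]), j = as.integer(sm[, 3]),
                       diameter_mm = sm[, 4])
  if (!length(sets)) {
    z <- nodes[, 3]
    sets <- list(cranial_surface = which(z > max(z) - 1e-9),
                 caudal_surface = which(z < min(z) + 1e-9),
                 screw_block = integer(0))
  }
  lat <- structure(list(nodes = nodes, struts = struts, sets = sets,
                        material = material, params = NULL),
                   class = "cage_lattice")
  validate_lattice(lat)
  lat
}

#' Export a lattice (and optional fields) as legacy VTK
#'
#' Writes an ASCII VTK legacy unstructured grid with the struts as line
#' cells; optional per-node point data (e.g. displacement) and per-strut cell
#' data (e.g. peak absolute principal strain) for visualization.
#'
#' @param lattice A `cage_lattice`.
#' @param path Output `.vtk` path.
#' @param point_data Optional named list of per-node vectors (length n) or
#'   n x 3 matrices (written as VECTORS).
#' @param cell_data Optional named list of per-strut vectors.
#' @return `path`, invisibly.
#' @export
write_lattice_vtk <- function(lattice, path, point_data = NULL,
                              cell_data = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(lattice$nodes); m <- nrow(lattice$struts)
  writeLines(c("# vtk DataFile Version 3.0",
               "trusscage lattice", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g %.10g", lattice$nodes[, 1],
                     lattice$nodes[, 2], lattice$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 3L * m), con)
  writeLines(sprintf("2 %d %d", lattice$struts$i - 1L,
                     lattice$struts$j - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("3", m), con)   # VTK_LINE
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
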