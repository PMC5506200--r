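#' Network node set with homotopic-pair structure
#'
#' @param labels character region names.
#' @param centers_mm numeric n x 3 matrix of MNI coordinates (mm).
#' @param hemisphere character vector, one of "L", "R", "M" per region.
#' @param pair_map integer two-column matrix; each row (i, j) marks region i
#'   and j as homotopic homologs. Indices must be distinct, used at most
#'   once, and paired regions must sit on opposite hemispheres.
#' @return An object of class \code{nodeset}.
#' @export
nodeset <- function(labels, centers_mm, hemisphere, pair_map) {
  n <- length(labels)
  centers_mm <- as.matrix(centers_mm)
  pair_map <- matrix(as.integer(pair_map), ncol = 2)
  stopifnot(nrow(centers_mm) == n, ncol(centers_mm) == 3,
            length(hemisphere) == n,
            all(hemisphere %in% c("L", "R", "M")),
            all(is.finite(centers_mm)))
  idx <- as.vector(pair_map)
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > n))
    stop("pair indices must be distinct, in 1..n, used at most once",
         call. = FALSE)
  hl <- hemisphere[pair_map[, 1]]; hr <- hemisphere[pair_map[, 2]]
  if (any(hl == hr) || any(hl == "M") || any(hr == "M"))
    stop("paired nodes must lie on opposite hemispheres", call. = FALSE)
  structure(list(labels = labels, centers_mm = centers_mm,
                 hemisphere = hemisphere, pair_map = pair_map),
            class = "nodeset")
}

#' @export
print.nodeset <- function(x, ...) {
  cat("nodeset:", length(x$labels), "regions,", nrow(x$pair_map),
      "homotopic pairs,",
      length(x$labels) - 2 * nrow(x$pair_map), "unpaired\n")
  invisible(x)
}

#' Homolog index per node
#'
#' @param nodes a \code{nodeset}.
#' @return integer vector: for each node, the index of its homotopic homolog,
#'   or \code{NA} for unpaired nodes.
#' @export
homolog_of <- function(nodes) {
  h <- rep(NA_integer_, length(nodes$labels))
  h[nodes$pair_map[, 1]] <- nodes$pair_map[, 2]
  h[nodes$pair_map[, 2]] <- nodes$pair_map[, 1]
  h
}

#' Default motor-network node set
#'
#' 28 regions: 12 mirrored homotopic pairs (SMA, CMA, PMd, PMv, SFG, SPL,
#' IPC, S2, anterior insula, putamen, caudate, cerebellar hemisphere) and 4
#' unpaired regions (M1, S1, thalamus — contralateral to the dominant foot —
#' and the midline cerebellar vermis). Coordinates are schematic MNI
#' placements spanning the cranial-caudal range, mirrored in x across
#' hemispheres, spaced so 3 mm spheres never overlap. They stand in for
#' activation-peak coordinates, which depend on data not available here.
#'
#' @return A \code{nodeset} with 28 nodes and 12 pairs.
#' @export
default_nodeset <- function() {
  pairs <- rbind(
    SMA  = c(6, -4, 60),
    CMA  = c(6, 2, 44),
    PMd  = c(26, -8, 56),
    PMv  = c(52, 4, 32),
    SFG  = c(20, 36, 44),
    SPL  = c(22, -54, 60),
    IPC  = c(48, -38, 48),
    S2   = c(54, -22, 18),
    INS  = c(36, 16, 4),
    PUT  = c(26, -2, 2),
    CAU  = c(14, 8, 10),
    CBH  = c(24, -58, -26))
  labels <- character(0); centers <- NULL; hemi <- character(0)
  pm <- NULL
  for (k in seq_len(nrow(pairs))) {
    nmL <- paste0(rownames(pairs)[k], "_L")
    nmR <- paste0(rownames(pairs)[k], "_R")
    cL <- pairs[k, ] * c(-1, 1, 1)
    labels <- c(labels, nmL, nmR)
    centers <- rbind(centers, cL, pairs[k, ])
    hemi <- c(hemi, "L", "R")
    pm <- rbind(pm, c(length(labels) - 1L, length(labels)))
  }
  uni <- rbind(M1_L = c(-8, -28, 66), S1_L = c(-10, -40, 64),
               THA_L = c(-12, -18, 8), VER_M = c(2, -62, -32))
  labels <- c(labels, rownames(uni))
  centers <- rbind(centers, uni)
  hemi <- c(hemi, "L", "L", "L", "M")
  rownames(centers) <- labels
  nodeset(labels, centers, hemi, pm)
}

#' Read a node table from TSV
#'
#' Expected columns: label, x, y, z, hemisphere, pair_id (empty or NA for
#' unpaired regions). A pair_id value must appear exactly twice.
#'
#' @param path TSV path.
#' @return A \code{nodeset}.
#' @export
read_nodeset <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pair_id = "character"))
  req <- c("label", "x", "y", "z", "hemisphere", "pair_id")
  if (!all(req %in% names(tb)))
    stop("node table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  pid <- tb$pair_id
  pid[is.na(pid) | pid == ""] <- NA
  tab <- table(pid[!is.na(pid)])
  bad <- names(tab)[tab != 2]
  if (length(bad))
    stop("pair_id not used exactly twice: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pm <- t(vapply(names(tab), function(id) which(!is.na(pid) & pid == id),
                 integer(2)))
  nodeset(tb$label, as.matrix(tb[, c("x", "y", "z")]), tb$hemisphere,
          if (length(tab)) pm else matrix(integer(0), ncol = 2))
}

#' Write a node set as TSV
#' @param nodes a \code{nodeset}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_nodeset <- function(nodes, path) {
  pid <- rep("", length(nodes$labels))
  for (k in seq_len(nrow(nodes$pair_map)))
    pid[nodes$pair_map[k, ]] <- sprintf("P%02d", k)
  utils::write.table(
    data.frame(label = nodes$labels, x = nodes$centers_mm[, 1],
               y = nodes$centers_mm[, 2], z = nodes$centers_mm[, 3],
               hemisphere = nodes$hemisphere, pair_id = pid,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
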