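#' Build a section adjacency network
#'
#' Constructs the areal support for the Leroux CAR prior: a set of roadway
#' sections with symmetric binary first-order adjacency (two sections are
#' neighbors when they share a common end).
#'
#' @param x One of: a single integer `M`, interpreted as a linear chain of
#'   `M` consecutive sections (the natural topology for a single freeway
#'   segmented along its length); a two-column matrix or data frame of edges
#'   given as pairs of section labels; or a square symmetric 0/1 adjacency
#'   matrix with zero diagonal.
#' @param labels Optional character vector of section labels. For a chain this
#'   names the sections in order; for an edge list it fixes the full section
#'   set (so isolated sections can exist); defaults to the labels present in
#'   the edges.
#' @return An object of class `section_network`: a list with elements `M`,
#'   `section_ids`, `adjacency` (symmetric 0/1 matrix with zero diagonal) and
#'   `neighbor_counts`.
#' @examples
#' net <- build_adjacency(5)
#' net$neighbor_counts
#' build_adjacency(cbind(c("a", "b"), c("b", "c")))
#' @export
build_adjacency <- function(x, labels = NULL) {
  if (is.numeric(x) && length(x) == 1L && is.null(dim(x))) {
    M <- as.integer(x)
    if (is.na(M) || M < 1L) stop("chain length must be a positive integer")
    if (is.null(labels)) labels <- as.character(seq_len(M))
    if (length(labels) != M) stop("'labels' must have length ", M)
    if (anyDuplicated(labels)) stop("duplicate section labels")
    A <- matrix(0L, M, M, dimnames = list(labels, labels))
    if (M > 1L) {
      idx <- seq_len(M - 1L)
      A[cbind(idx, idx + 1L)] <- 1L
      A[cbind(idx + 1L, idx)] <- 1L
    }
    return(new_section_network(A))
  }
  if (is.matrix(x) && nrow(x) == ncol(x) && nrow(x) > 2L &&
      all(x %in% c(0, 1)) && !is.null(rownames(x))) {
    return(section_network_from_matrix(x))
  }
  if ((is.matrix(x) || is.data.frame(x)) && ncol(x) == 2L) {
    edges <- as.matrix(x)
    storage.mode(edges) <- "character"
    if (is.null(labels)) labels <- unique(as.character(t(edges)))
    if (anyDuplicated(labels)) stop("duplicate section labels")
    bad <- setdiff(as.character(edges), labels)
    if (length(bad))
      stop("edge references unknown section label(s): ",
           paste(unique(bad), collapse = ", "))
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-edges are not allowed (a section cannot neighbor itself)")
    M <- length(labels)
    A <- matrix(0L, M, M, dimnames = list(labels, labels))
    A[cbind(match(edges[, 1L], labels), match(edges[, 2L], labels))] <- 1L
    A[cbind(match(edges[, 2L], labels), match(edges[, 1L], labels))] <- 1L
    return(new_section_network(A))
  }
  if (is.matrix(x) && nrow(x) == ncol(x)) return(section_network_from_matrix(x))
  stop("'x' must be a chain length, a two-column edge list, ",
       "or a square adjacency matrix")
}

section_network_from_matrix <- function(A) {
  if (!isTRUE(all.equal(unname(A), unname(t(A)))))
    stop("adjacency matrix must be symmetric")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero (no self-edges)")
  if (is.null(rownames(A))) {
    dimnames(A) <- list(as.character(seq_len(nrow(A))),
                        as.character(seq_len(nrow(A))))
  }
  if (anyDuplicated(rownames(A))) stop("duplicate section labels")
  storage.mode(A) <- "integer"
  new_section_network(A)
}

new_section_network <- function(A) {
  structure(list(M = nrow(A),
                 section_ids = rownames(A),
                 adjacency = A,
                 neighbor_counts = as.integer(rowSums(A))),
            class = "section_network")
}

#' @export
print.section_network <- function(x, ...) {
  cat("Section network:", x$M, "sections,", sum(x$adjacency) / 2L, "edges\n")
  cat("Neighbor counts: min", min(x$neighbor_counts),
      "max", max(x$neighbor_counts), "\n")
  invisible(x)
}

#' Read a section network from a plain-text file
#'
#' Accepts either a whitespace-delimited edge list (one `"m n"` pair of
#' section labels per line) or the shorthand `chain: M` on the first line for
#' a linear chain of `M` sections. Blank lines and `#` comments are ignored.
#'
#' @param path Path to the file.
#' @return A [build_adjacency()] `section_network`.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty adjacency file: ", path)
  if (grepl("^chain\\s*:", lines[1L])) {
    M <- as.integer(trimws(sub("^chain\\s*:", "", lines[1L])))
    return(build_adjacency(M))
  }
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) != 2L))
    stop("each edge line must contain exactly two section labels")
  build_adjacency(do.call(rbind, parts))
}

check_leroux_params <- function(rho, delta) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho > 1)
    stop("'rho' must be a single value in [0, 1]")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("'delta' must be a single positive value")
}

#' Leroux CAR full conditional for one section
#'
#' Conditional law of a section effect given all others under the Leroux
#' conditional autoregressive prior: the effect of section `m` is normal with
#' mean `rho * sum(w[m, ] * phi) / (1 - rho + rho * d_m)` and variance
#' `delta^2 / (1 - rho + rho * d_m)` where `d_m` is its neighbor count.
#' `rho = 0` gives independent N(0, delta^2) effects; `rho = 1` recovers the
#' intrinsic CAR conditional (neighbor average, variance `delta^2 / d_m`).
#'
#' @param m Section index or label.
#' @param phi Numeric vector of all section effects (the value at position
#'   `m` is ignored).
#' @param rho Spatial-correlation strength in `[0, 1]`.
#' @param delta Conditional scale hyper-parameter, positive.
#' @param network A `section_network`.
#' @return A list with elements `mean` and `variance`.
#' @export
leroux_conditional <- function(m, phi, rho, delta, network) {
  check_leroux_params(rho, delta)
  if (is.character(m)) m <- match(m, network$section_ids)
  if (is.na(m) || m < 1L || m > network$M) stop("unknown section 'm'")
  if (length(phi) != network$M)
    stop("'phi' must have one value per section")
  w <- network$adjacency[m, ]
  denom <- 1 - rho + rho * sum(w)
  list(mean = rho * sum(w * phi) / denom, variance = delta^2 / denom)
}

#' Leroux CAR precision matrix
#'
#' The joint precision implied by the full-conditional specification:
#' `Q = (rho * (D - W) + (1 - rho) * I) / delta^2`, where `W` is the binary
#' adjacency and `D = diag(neighbor_counts)`. Proper (positive definite) for
#' `rho < 1`; singular in the intrinsic-CAR limit `rho = 1`.
#'
#' @inheritParams leroux_conditional
#' @return An `M x M` precision matrix.
#' @export
leroux_precision <- function(rho, delta, network) {
  check_leroux_params(rho, delta)
  W <- network$adjacency
  D <- diag(network$neighbor_counts, network$M)
  (rho * (D - W) + (1 - rho) * diag(network$M)) / delta^2
}

#' Joint log-density of Leroux CAR section effects
#'
#' Evaluates the zero-mean multivariate normal log-density with precision
#' [leroux_precision()]. Requires `rho < 1`; the intrinsic-CAR boundary has an
#' improper joint and is rejected here (it is supported only through the
#' conditional updates used in sampling).
#'
#' @param phi Numeric vector of section effects (length `M`).
#' @inheritParams leroux_conditional
#' @return The joint log-density (a scalar).
#' @export
leroux_logdensity <- function(phi, rho, delta, network) {
  check_leroux_params(rho, delta)
  if (rho >= 1)
    stop("rho = 1 gives an improper joint density; ",
         "the intrinsic-CAR limit is only defined conditionally")
  if (length(phi) != network$M)
    stop("'phi' must have one value per section")
  Q <- leroux_precision(rho, delta, network)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  -0.5 * network$M * log(2 * pi) + 0.5 * sum(log(ev)) -
    0.5 * drop(crossprod(phi, Q %*% phi))
}

#' Segment roadway geometry into homogeneous sections
#'
#' Merges consecutive geometry intervals into sections that are homogeneous
#' in horizontal curvature and vertical grade: a new section starts whenever
#' either attribute moves away from the running section's reference value by
#' more than its tolerance. With zero tolerances (the default) every change
#' point starts a new section.
#'
#' @param geometry Data frame with columns `start_km`, `end_km`, `curvature`
#'   (0.1 km^-1 units) and `grade` (percent), ordered along the roadway and
#'   tiling it without overlap.
#' @param tol_curvature,tol_grade Non-negative merge tolerances.
#' @return A data frame of sections with columns `section_id`, `start_km`,
#'   `end_km`, `curvature`, `grade` (attribute values of the section's first
#'   interval).
#' @export
segment_by_homogeneity <- function(geometry, tol_curvature = 0,
                                   tol_grade = 0) {
  need <- c("start_km", "end_km", "curvature", "grade")
  miss <- setdiff(need, names(geometry))
  if (length(miss)) stop("geometry is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(geometry) == 0L) stop("empty geometry table")
  if (any(geometry$end_km <= geometry$start_km))
    stop("each interval must have end_km > start_km")
  if (is.unsorted(geometry$start_km, strictly = TRUE))
    stop("geometry intervals must be ordered by start_km")
  if (nrow(geometry) > 1L) {
    gap <- geometry$start_km[-1L] - geometry$end_km[-nrow(geometry)]
    if (any(abs(gap) > 1e-9))
      stop("geometry intervals must tile the roadway without gaps or overlap")
  }
  ref_c <- geometry$curvature[1L]
  ref_g <- geometry$grade[1L]
  seg <- integer(nrow(geometry))
  seg[1L] <- 1L
  for (i in seq_len(nrow(geometry))[-1L]) {
    if (abs(geometry$curvature[i] - ref_c) > tol_curvature ||
        abs(geometry$grade[i] - ref_g) > tol_grade) {
      seg[i] <- seg[i - 1L] + 1L
      ref_c <- geometry$curvature[i]
      ref_g <- geometry$grade[i]
    } else {
      seg[i] <- seg[i - 1L]
    }
  }
  first <- !duplicated(seg)
  data.frame(section_id = as.character(unique(seg)),
             start_km = geometry$start_km[first],
             end_km = geometry$end_km[rev(!duplicated(rev(seg)))],
             curvature = geometry$curvature[first],
             grade = geometry$grade[first],
             stringsAsFactors = FALSE)
}

#' Assign crash locations to sections
#'
#' Each crash is assigned to the section whose half-open interval
#' `[start_km, end_km)` contains its kilometer marker, so assignment at
#' section boundaries is unique; the final section is closed on the right so
#' the roadway's endpoint remains assignable.
#'
#' @param km Numeric vector of crash kilometer markers.
#' @param sections Section table as returned by [segment_by_homogeneity()].
#' @return Character vector of section ids, one per crash.
#' @export
assign_sections <- function(km, sections) {
  if (any(km < sections$start_km[1L] | km > sections$end_km[nrow(sections)]))
    stop("crash location outside the segmented roadway")
  idx <- findInterval(km, c(sections$start_km, sections$end_km[nrow(sections)]),
                      rightmost.closed = TRUE)
  sections$section_id[idx]
}
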