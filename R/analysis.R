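new_band_matrix <- function(x) {
  stopifnot(all(c("variety", "group") %in% names(x)))
  class(x) <- c("band_matrix", class(tibble::tibble()))
  x
}

marker_cols <- function(bm) setdiff(names(bm), c("variety", "group"))

#' Read a binary band matrix from TSV
#'
#' Layout: one row per variety; columns `variety`, `group`, then one
#' column per marker with entries `0`, `1` or `.` (missing, stored as
#' `NA`). Any other entry is rejected with its cell coordinates.
#'
#' @param path TSV path.
#' @return A `band_matrix` tibble.
#' @export
read_band_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("variety", "group") %in% names(x))) {
    stop("band matrix needs 'variety' and 'group' columns", call. = FALSE)
  }
  for (m in marker_cols(x)) {
    bad <- !(x[[m]] %in% c("0", "1", ".") | is.na(x[[m]]))
    if (any(bad)) {
      i <- which(bad)[1]
      stop("invalid band entry '", x[[m]][i], "' at variety '",
           x$variety[i], "', marker '", m, "' (allowed: 0, 1, .)",
           call. = FALSE)
    }
    x[[m]] <- ifelse(x[[m]] == ".", NA_integer_,
                     suppressWarnings(as.integer(x[[m]])))
  }
  if (anyDuplicated(x$variety)) {
    stop("duplicated variety ids in band matrix", call. = FALSE)
  }
  new_band_matrix(x)
}

#' Write a band matrix to TSV (missing as ".")
#'
#' @param bm A `band_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(bm, path) {
  out <- bm
  for (m in marker_cols(out)) {
    out[[m]] <- ifelse(is.na(out[[m]]), ".", as.character(out[[m]]))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Per-marker discrimination report for a genotyped panel
#'
#' A marker discriminates the two groups when its non-missing scores are
#' constant within each group and differ between the groups. Varieties
#' carrying the out-of-group allele (their score equals the other group's
#' majority score) are listed per marker.
#'
#' @param bm A `band_matrix` with group labels.
#' @return A `discrimination_report`: list with `per_marker` (`marker`,
#'   `classification`, `out_of_group`), and `summary` (counts and the
#'   fraction of discriminating markers).
#' @export
discrimination_report <- function(bm) {
  groups <- unique(bm$group)
  if (length(groups) != 2 || anyNA(bm$group)) {
    stop("band matrix must carry exactly two non-missing group labels",
         call. = FALSE)
  }
  per_marker <- purrr::map(marker_cols(bm), function(m) {
    v <- bm[[m]]
    a <- v[bm$group == groups[1]]
    b <- v[bm$group == groups[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) + length(b) == 0) {
      return(tibble::tibble(marker = m, classification = "uninformative",
                            out_of_group = NA_character_))
    }
    cls <- if (length(unique(c(a, b))) == 1) {
      "not_discriminating"
    } else if (length(unique(a)) == 1 && length(unique(b)) == 1 &&
               a[1] != b[1]) {
      "discriminating"
    } else {
      "not_discriminating"
    }
    # varieties whose score matches the other group's majority score
    maj <- function(x) if (length(x)) as.integer(names(which.max(table(x)))) else NA_integer_
    maj_a <- maj(a); maj_b <- maj(b)
    oog <- bm$variety[
      (!is.na(bm[[m]])) &
        ((bm$group == groups[1] & !is.na(maj_b) & bm[[m]] == maj_b &
            !is.na(maj_a) & maj_a != maj_b) |
         (bm$group == groups[2] & !is.na(maj_a) & bm[[m]] == maj_a &
            !is.na(maj_b) & maj_a != maj_b))
    ]
    tibble::tibble(marker = m, classification = cls,
                   out_of_group = if (length(oog)) paste(oog, collapse = ",")
                                  else NA_character_)
  }) |> purrr::list_rbind()
  n_disc <- sum(per_marker$classification == "discriminating")
  structure(
    list(
      per_marker = per_marker,
      summary = tibble::tibble(
        n_markers = nrow(per_marker),
        n_discriminating = n_disc,
        fraction_discriminating = n_disc / nrow(per_marker)
      )
    ),
    class = "discrimination_report"
  )
}

#' @export
print.discrimination_report <- function(x, ...) {
  s <- x$summary
  cat("<discrimination_report> ", s$n_discriminating, "/", s$n_markers,
      " markers discriminate the two groups (",
      round(100 * s$fraction_discriminating, 1), "%)\n", sep = "")
  invisible(x)
}

#' @rdname discrimination_report
#' @param x A `discrimination_report`.
#' @param ... Unused.
#' @export
tidy.discrimination_report <- function(x, ...) x$per_marker

#' @rdname discrimination_report
#' @export
glance.discrimination_report <- function(x, ...) x$summary

#' Genetic distance between varieties from band scores
#'
#' Simple-matching distance by default: the fraction of markers, among
#' those scored in both varieties, at which the two differ. Jaccard
#' (mismatches over markers where at least one variety shows the band) is
#' available as an option. Pairs with no comparable marker get `NA`
#' (an error in `strict` mode).
#'
#' @param bm A `band_matrix`.
#' @param method `"simple_matching"` or `"jaccard"`.
#' @param strict Error on pairs with zero comparable markers.
#' @return A `band_dist`: symmetric numeric matrix in `[0, 1]` with zero
#'   diagonal, varieties as dimnames, attribute `groups`.
#' @export
genetic_distance <- function(bm, method = c("simple_matching", "jaccard"),
                             strict = FALSE) {
  method <- match.arg(method)
  if (nrow(bm) < 2) stop("need at least 2 varieties", call. = FALSE)
  mat <- as.matrix(bm[, marker_cols(bm)])
  rownames(mat) <- bm$variety
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(bm$variety, bm$variety))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- mat[i, ]; xj <- mat[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      if (method == "jaccard") ok <- ok & (xi == 1 | xj == 1)
      if (!any(ok)) {
        if (strict) {
          stop("no comparable markers between '", bm$variety[i], "' and '",
               bm$variety[j], "'", call. = FALSE)
        }
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- mean(xi[ok] != xj[ok])
      }
    }
  }
  structure(d, groups = setNames(bm$group, bm$variety),
            method = method, class = c("band_dist", "matrix"))
}

#' @rdname genetic_distance
#' @param x A `band_dist` matrix.
#' @param ... Unused.
#' @export
tidy.band_dist <- function(x, ...) {
  m <- unclass(x)
  attr(m, "groups") <- NULL
  attr(m, "method") <- NULL
  tibble::as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal") |>
    setNames(c("variety_a", "variety_b", "distance")) |>
    dplyr::filter(as.character(.data$variety_a) < as.character(.data$variety_b)) |>
    dplyr::mutate(variety_a = as.character(.data$variety_a),
                  variety_b = as.character(.data$variety_b))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage (UPGMA) clustering of the varieties; ties are broken
#' deterministically by sorting varieties lexicographically before
#' clustering. Output is a rooted ultrametric tree in Newick form, leaf
#' branch lengths summing root-to-tip to half the joining distance (two
#' varieties at distance d yield `(A:d/2,B:d/2);`).
#'
#' @param dist A `band_dist` (or any symmetric distance matrix with
#'   dimnames); must be complete (no `NA`).
#' @return Newick string (single line, terminated by `;`).
#' @export
upgma_tree <- function(dist) {
  m <- unclass(dist)
  if (anyNA(m)) stop("distance matrix has missing entries", call. = FALSE)
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- hclust(as.dist(m), method = "average")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}
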