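#' Six-connected components of a hypointensity mask
#'
#' Decomposes a binary mask into maximal face-connected (6-neighbourhood)
#' components — one component per individual hypointensity. Components are
#' ordered deterministically by their minimum linear voxel index in array
#' order (x fastest, then y, then z), so the result does not depend on any
#' internal traversal order.
#'
#' @param hypo a binary [voxel_grid] mask.
#' @return An object of class `component_set`: a list with a `components`
#'   tibble (`component`, `n_voxels`, `voxels` list-column of linear voxel
#'   indices), the grid `shape` and `voxel_size`, and `labeled = FALSE`.
#' @export
connected_components <- function(hypo) {
  stopifnot_mask(hypo)
  shp <- vg_shape(hypo)
  set <- which(hypo$values > 0L)
  if (length(set) == 0L) {
    return(structure(list(
      components = tibble::tibble(component = integer(), n_voxels = integer(),
                                  voxels = list()),
      shape = shp, voxel_size = hypo$voxel_size, labeled = FALSE
    ), class = "component_set"))
  }
  vid <- integer(prod(shp))
  vid[set] <- seq_along(set)
  strides <- c(1L, shp[1], shp[1] * shp[2])
  coord <- arrayInd(set, shp)
  edges <- list()
  for (a in 1:3) {
    ok <- coord[, a] < shp[a]
    nb <- set[ok] + strides[a]
    has <- vid[nb] > 0L
    if (any(has))
      edges[[a]] <- cbind(vid[set[ok][has]], vid[nb[has]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(set), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  grp <- split(set, memb)
  ord <- order(vapply(grp, min, numeric(1)))
  grp <- grp[ord]
  structure(list(
    components = tibble::tibble(
      component = seq_along(grp),
      n_voxels = unname(lengths(grp)),
      voxels = unname(grp)
    ),
    shape = shp, voxel_size = hypo$voxel_size, labeled = FALSE
  ), class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components on %s grid%s\n",
              nrow(x$components), paste(x$shape, collapse = "x"),
              if (isTRUE(x$labeled)) " (labeled)" else ""))
  invisible(x)
}

#' Assign structure labels to components
#'
#' Labels each component by maximal intersection with the structure masks. A
#' component overlapping the union of structure masks by less than 50% of its
#' voxels is labeled `outside` (code 0) and excluded from downstream burden,
#' morphology and intensity statistics; "at least 50%" is implemented as
#' `>= 0.5`, so a component exactly half inside is labeled. On an exact tie of
#' the maximal intersection, the label of the structure containing the
#' component's most hypointense (minimum standardized T2*w) voxel among the
#' tied structures is chosen and the `tie_broken` flag set; if that voxel lies
#' in none of the tied structures the lowest tied code is used with a warning.
#'
#' Labeling is invariant to the order in which structure masks are supplied.
#'
#' @param cs a `component_set` from [connected_components()].
#' @param structures named list (names = label codes as character) of binary
#'   [voxel_grid] masks, co-registered with the component grid. Masks must be
#'   pairwise disjoint.
#' @param t2sw standardized T2*w intensity [voxel_grid] used for tie-breaking.
#' @param min_fraction overlap fraction below which a component is `outside`.
#' @return The `component_set` with `label` (integer code, 0 = outside) and
#'   `tie_broken` columns, `labeled = TRUE`.
#' @export
assign_labels <- function(cs, structures, t2sw, min_fraction = 0.5) {
  stopifnot(inherits(cs, "component_set"))
  codes <- as.integer(names(structures))
  if (anyNA(codes)) stop("`structures` must be named by integer label codes", call. = FALSE)
  lab_arr <- array(0L, dim = cs$shape)
  for (i in seq_along(structures)) {
    m <- structures[[i]]
    stopifnot_mask(m)
    if (!identical(dim(m$values), as.integer(cs$shape)) &&
        !identical(dim(m$values), cs$shape))
      stop("structure mask shape differs from component grid", call. = FALSE)
    sel <- m$values > 0L
    if (any(lab_arr[sel] != 0L))
      stop("structure masks overlap; labels must be disjoint", call. = FALSE)
    lab_arr[sel] <- codes[i]
  }
  tvals <- t2sw$values
  n <- nrow(cs$components)
  label <- integer(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    vox <- cs$components$voxels[[i]]
    lv <- lab_arr[vox]
    inside <- lv != 0L
    if (sum(inside) / length(vox) < min_fraction) {
      label[i] <- 0L
      next
    }
    cnt <- table(lv[inside])
    mx <- max(cnt)
    tied <- sort(as.integer(names(cnt)[cnt == mx]))
    if (length(tied) == 1L) {
      label[i] <- tied
    } else {
      tie[i] <- TRUE
      dark <- vox[which.min(tvals[vox])]
      dark_code <- lab_arr[dark]
      if (dark_code %in% tied) {
        label[i] <- dark_code
      } else {
        warning("tie between structures but darkest voxel in neither; using lowest code")
        label[i] <- tied[1]
      }
    }
  }
  cs$components$label <- label
  cs$components$tie_broken <- tie
  cs$labeled <- TRUE
  cs
}

#' Extract one component as a mask
#'
#' @param cs a `component_set`.
#' @param component component id.
#' @return A binary [voxel_grid] mask on the component grid.
#' @export
component_mask <- function(cs, component) {
  stopifnot(inherits(cs, "component_set"))
  row <- cs$components[cs$components$component == component, ]
  if (nrow(row) != 1L) stop("unknown component id", call. = FALSE)
  arr <- array(0L, dim = cs$shape)
  arr[row$voxels[[1]]] <- 1L
  voxel_grid(arr, voxel_size = cs$voxel_size, kind = "mask")
}

#' Component table for export
#'
#' @param cs a labeled `component_set`.
#' @param subject_id id recorded in the table.
#' @return A tibble (`subject_id`, `component`, `label`, `structure`,
#'   `n_voxels`, `tie_broken`).
#' @export
component_table <- function(cs, subject_id = NA_character_) {
  stopifnot(isTRUE(cs$labeled))
  tibble::tibble(subject_id = subject_id,
                 component = cs$components$component,
                 label = cs$components$label,
                 structure = structure_name(cs$components$label),
                 n_voxels = cs$components$n_voxels,
                 tie_broken = cs$components$tie_broken)
}

#' Labeled component map as an integer volume
#'
#' @param cs a labeled `component_set`.
#' @return A label-kind [voxel_grid] whose voxels carry the component id.
#' @export
component_label_map <- function(cs) {
  arr <- array(0L, dim = cs$shape)
  for (i in seq_len(nrow(cs$components)))
    arr[cs$components$voxels[[i]]] <- cs$components$component[i]
  voxel_grid(arr, voxel_size = cs$voxel_size, kind = "label")
}

#' Pool component counts by structure
#'
#' Tallies labeled components across subjects into the input format of
#' [structure_fraction_report()].
#'
#' @param cs_list list of labeled `component_set` objects.
#' @return A tibble (`region`, `location`, `count`).
#' @export
count_components_by_structure <- function(cs_list) {
  if (inherits(cs_list, "component_set")) cs_list <- list(cs_list)
  labs <- unlist(lapply(cs_list, function(cs) cs$components$label))
  lab_tbl <- bg_labels()
  codes <- sort(unique(labs))
  tibble::tibble(
    region = ifelse(codes == 0L, "outside",
                    lab_tbl$structure[match(codes, lab_tbl$code)]),
    location = ifelse(codes == 0L, "outside", "inside"),
    count = as.integer(vapply(codes, function(cd) sum(labs == cd), integer(1)))
  ) |>
    dplyr::count(.data$region, .data$location, wt = .data$count, name = "count")
}

#' Per-structure component fractions
#'
#' Given pooled per-region component counts — either tallied from labeled
#' component sets via [count_components_by_structure()] or supplied directly
#' (e.g. from a published table) — reports each region's percentage of its
#' location total (inside vs outside the basal ganglia / internal capsule),
#' rounded to the nearest integer percent, together with the totals.
#'
#' @param counts a tibble/data frame with columns `region`, `location`
#'   (`"inside"` or `"outside"`), `count`; or a list of labeled
#'   `component_set`s.
#' @return A tibble with `region`, `location`, `count`, `total` (per
#'   location), and integer `percent`.
#' @export
structure_fraction_report <- function(counts) {
  if (inherits(counts, "component_set") ||
      (is.list(counts) && !is.data.frame(counts)))
    counts <- count_components_by_structure(counts)
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("region", "location", "count") %in% names(counts)))
  counts |>
    dplyr::group_by(.data$location) |>
    dplyr::mutate(total = sum(.data$count),
                  percent = as.integer(round(100 * .data$count / .data$total))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$location, dplyr::desc(.data$count))
}
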