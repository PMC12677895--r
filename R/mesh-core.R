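# Mesh topology shared by every stage: 9 nodes on a 3 column x 3 level grid,
# 8 triangular facets (2 per layer x flank quad). The triangulation is fixed
# so that facet k always spans the same (column, level) node ids in every
# mesh, making per-facet comparisons across frames and phases well-defined.

RIDGE_COLUMNS <- c("proximal_valley", "crest", "distal_valley")
RIDGE_LEVELS  <- c("surface", "sc_ve", "ed_junction")

#' @rdname build_ridge_mesh
#' @export
ridge_node_names <- function() {
  as.vector(outer(RIDGE_LEVELS, RIDGE_COLUMNS,
                  function(l, c) paste(c, l, sep = ".")))
}

# Each quad (layer x flank) is split along its valley-bottom to crest-top
# diagonal; vertices ordered counter-clockwise in (x right, y up) terms.
ridge_facet_table <- local({
  nd <- function(col, lev) paste(col, lev, sep = ".")
  quad <- function(layer, flank) {
    valley <- if (flank == "proximal") "proximal_valley" else "distal_valley"
    up  <- if (layer == "stratum_corneum") "surface" else "sc_ve"
    low <- if (layer == "stratum_corneum") "sc_ve" else "ed_junction"
    vl <- nd(valley, low); vu <- nd(valley, up)
    cu <- nd("crest", up); cl <- nd("crest", low)
    if (flank == "proximal") {
      # valley on the left: CCW (y-up) orders below
      rbind(c(vl, cu, vu), c(vl, cl, cu))
    } else {
      # valley on the right: mirror image, reverse order to keep CCW
      rbind(c(vl, vu, cu), c(vl, cu, cl))
    }
  }
  tab <- do.call(rbind, lapply(c("stratum_corneum", "viable_epidermis"),
    function(layer) do.call(rbind, lapply(c("proximal", "distal"),
      function(flank) {
        v <- quad(layer, flank)
        data.frame(layer = layer, flank = flank,
                   v1 = v[, 1], v2 = v[, 2], v3 = v[, 3],
                   stringsAsFactors = FALSE)
      }))))
  tab <- cbind(facet_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
})

#' Facet topology of the per-ridge mesh
#'
#' Returns the fixed triangulation used for every ridge mesh: 8 facets, two
#' per (layer, flank) quad, each quad split along its valley-bottom to
#' crest-top diagonal. Vertex columns `v1..v3` hold node names
#' (`"<column>.<level>"`), ordered counter-clockwise when y points up.
#'
#' @return A data frame with columns `facet_id`, `layer`
#'   (`stratum_corneum`/`viable_epidermis`), `flank` (`proximal`/`distal`),
#'   and vertex node names `v1`, `v2`, `v3`.
#' @export
facet_topology <- function() ridge_facet_table

new_ridge_mesh <- function(nodes) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 2,
            setequal(rownames(nodes), ridge_node_names()))
  nodes <- nodes[ridge_node_names(), , drop = FALSE]
  colnames(nodes) <- c("x", "y")
  structure(list(nodes = nodes, facets = ridge_facet_table),
            class = "ridge_mesh")
}

facet_vertices <- function(mesh, facet_id) {
  f <- mesh$facets[facet_id, ]
  mesh$nodes[c(f$v1, f$v2, f$v3), , drop = FALSE]
}

# Signed facet area in (x, y-up) terms; positive for the canonical winding.
facet_signed_area <- function(mesh, facet_id) {
  p <- facet_vertices(mesh, facet_id)
  p[, 2] <- -p[, 2]                      # stored y grows downward
  0.5 * ((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
         (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
}

facet_areas <- function(mesh) {
  vapply(mesh$facets$facet_id, function(k) facet_signed_area(mesh, k),
         numeric(1))
}

#' @export
print.ridge_mesh <- function(x, ...) {
  w <- tryCatch(ridge_width(x), error = function(e) NA_real_)
  cat("Ridge mesh: 9 nodes, 8 facets\n")
  cat(sprintf("  width (valley to valley, surface): %.3f mm\n", w))
  cat(sprintf("  SC thickness: %.3f mm, VE thickness: %.3f mm\n",
              layer_thickness(x, "stratum_corneum"),
              layer_thickness(x, "viable_epidermis")))
  invisible(x)
}

#' @export
plot.ridge_mesh <- function(x, add = FALSE, col = c(stratum_corneum = "#4477AA",
                            viable_epidermis = "#CCAA44"), asp = 1, ...) {
  nodes <- x$nodes
  if (!add) {
    plot(nodes[, 1], -nodes[, 2], type = "n", asp = asp,
         xlab = "x (mm, distal +)", ylab = "height (mm)", ...)
  }
  for (k in x$facets$facet_id) {
    p <- facet_vertices(x, k)
    polygon(p[, 1], -p[, 2], border = col[[x$facets$layer[k]]])
  }
  invisible(x)
}

#' Parameters of the synthetic ridge geometry
#'
#' Bundles the dimensions of the synthetic reference ridge profile. Defaults
#' correspond to the average geometry reported for lightly loaded fingerpad
#' skin: 0.47 mm ridge width, 0.38 mm stratum corneum and 0.12 mm viable
#' epidermis thickness.
#'
#' @param ridge_width Valley-to-valley ridge width at the surface, mm.
#' @param sc_thickness Stratum corneum thickness, mm.
#' @param ve_thickness Viable epidermis thickness, mm.
#' @param n_ridges Number of adjacent ridges to generate (neighbours share
#'   their valley landmark).
#' @param crest_height Surface undulation amplitude, mm: the crest column sits
#'   this much above the valleys.
#' @return An object of class `ridge_geometry_params`.
#' @export
ridge_geometry_params <- function(ridge_width = 0.47, sc_thickness = 0.38,
                                  ve_thickness = 0.12, n_ridges = 8,
                                  crest_height = 0.05) {
  if (!all(c(ridge_width, sc_thickness, ve_thickness) > 0))
    stop("all lengths must be > 0", call. = FALSE)
  if (crest_height < 0) stop("crest_height must be >= 0", call. = FALSE)
  if (n_ridges < 1) stop("n_ridges must be >= 1", call. = FALSE)
  structure(list(ridge_width = ridge_width, sc_thickness = sc_thickness,
                 ve_thickness = ve_thickness, n_ridges = as.integer(n_ridges),
                 crest_height = crest_height),
            class = "ridge_geometry_params")
}

#' Generate the reference configuration of synthetic ridges
#'
#' Lays out `n_ridges` adjacent ridge meshes along the lateral axis. Each
#' ridge has nine nodes on a 3-column (proximal valley, crest, distal valley)
#' by 3-level (surface, SC/VE border, epidermis-dermis junction) grid; the
#' crest column is elevated by `crest_height` and, within each column, the
#' level spacing equals the stratum corneum and viable epidermis thicknesses.
#' Adjacent ridges share their valley landmark (the distal valley of ridge i
#' coincides with the proximal valley of ridge i+1).
#'
#' @param params A [ridge_geometry_params()] object.
#' @return A list of `ridge_mesh` objects, one per ridge, in mm; y grows
#'   downward with the valley surface at y = 0.
#' @export
generate_ridge_geometry <- function(params = ridge_geometry_params()) {
  stopifnot(inherits(params, "ridge_geometry_params"))
  w <- params$ridge_width
  lapply(seq_len(params$n_ridges), function(i) {
    xs <- c(proximal_valley = (i - 1) * w, crest = (i - 0.5) * w,
            distal_valley = i * w)
    surf_y <- c(proximal_valley = 0, crest = -params$crest_height,
                distal_valley = 0)
    nodes <- do.call(rbind, lapply(RIDGE_COLUMNS, function(col) {
      ys <- surf_y[[col]] +
        cumsum(c(0, params$sc_thickness, params$ve_thickness))
      m <- cbind(x = rep(xs[[col]], 3), y = ys)
      rownames(m) <- paste(col, RIDGE_LEVELS, sep = ".")
      m
    }))
    new_ridge_mesh(nodes)
  })
}
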