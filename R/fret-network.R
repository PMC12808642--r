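## Transition dipoles, orientation factors, Forster rates, and the
## excitation-energy-transfer network.

#' Qy transition dipoles from NB/ND coordinates
#'
#' The chlorophyll a Qy transition dipole is approximated by the unit vector
#' along the NB to ND axis of the chlorin ring. The NB -> ND sign convention
#' is arbitrary: the orientation factor kappa^2 is invariant under flipping
#' either dipole.
#'
#' @param model a \code{ComplexModel}, or a pigment data.frame.
#' @return data.frame: \code{pigment_id}, \code{ux}, \code{uy}, \code{uz}.
#' @export
transitionDipoles <- function(model) {
  p <- if (is(model, "ComplexModel")) pigments(model) else model
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  if (!nrow(chl))
    return(data.frame(pigment_id = character(), ux = numeric(),
                      uy = numeric(), uz = numeric(), stringsAsFactors = FALSE))
  v <- as.matrix(chl[, c("nd_x", "nd_y", "nd_z")]) -
       as.matrix(chl[, c("nb_x", "nb_y", "nb_z")])
  nv <- rowNorms(v)
  if (any(nv == 0))
    stop("degenerate dipole (NB == ND) for: ",
         paste(chl$pigment_id[nv == 0], collapse = ", "))
  u <- v / nv
  data.frame(pigment_id = chl$pigment_id, ux = u[, 1], uy = u[, 2],
             uz = u[, 3], stringsAsFactors = FALSE)
}

#' Orientation factor kappa^2
#'
#' kappa^2 = [u_D . u_A - 3 (u_D . r_hat)(u_A . r_hat)]^2 for unit donor and
#' acceptor dipoles and the unit vector r_hat from donor to acceptor Mg.
#' Vectorized over rows; the result lies in [0, 4].
#'
#' @param u_d,u_a unit 3-vectors (or n x 3 matrices) for donor/acceptor
#'   dipoles.
#' @param r_vec donor-to-acceptor displacement(s), any positive length.
#' @return numeric vector of kappa^2 values.
#' @export
kappaSquared <- function(u_d, u_a, r_vec) {
  u_d <- matrix(u_d, ncol = 3); u_a <- matrix(u_a, ncol = 3)
  r_vec <- matrix(r_vec, ncol = 3)
  rn <- rowNorms(r_vec)
  if (any(rn == 0)) stop("zero-length donor-acceptor vector")
  rh <- r_vec / rn
  k <- rowSums(u_d * u_a) - 3 * rowSums(u_d * rh) * rowSums(u_a * rh)
  k^2
}

#' Pairwise Forster rate between two chlorophylls
#'
#' k = C kappa^2 / (n^4 R^6) with R the Mg-Mg distance in nanometres, giving
#' the rate in ps^-1 and the lifetime 1/k in ps (infinite when kappa^2 = 0).
#'
#' @param donor,acceptor single-row chlorophyll pigment records (as in
#'   \code{pigments(model)}).
#' @param params a \code{\link{FretParameters}}.
#' @return one-row data.frame: \code{donor}, \code{acceptor}, \code{R}
#'   (Angstrom), \code{kappa_sq}, \code{rate} (ps^-1), \code{lifetime} (ps).
#' @export
fretRate <- function(donor, acceptor, params = FretParameters()) {
  stopifnot(nrow(donor) == 1, nrow(acceptor) == 1)
  dm <- as.numeric(donor[, c("x", "y", "z")])
  am <- as.numeric(acceptor[, c("x", "y", "z")])
  r_vec <- am - dm
  R <- vecNorm(r_vec)
  if (R == 0) stop("coincident Mg atoms for ", donor$pigment_id, " and ",
                   acceptor$pigment_id)
  ud <- unitVector(as.numeric(donor[, c("nd_x", "nd_y", "nd_z")]) -
                   as.numeric(donor[, c("nb_x", "nb_y", "nb_z")]))
  ua <- unitVector(as.numeric(acceptor[, c("nd_x", "nd_y", "nd_z")]) -
                   as.numeric(acceptor[, c("nb_x", "nb_y", "nb_z")]))
  k2 <- kappaSquared(ud, ua, r_vec)
  rate <- params@C * k2 / (params@n^4 * (R / 10)^6)
  data.frame(donor = donor$pigment_id, acceptor = acceptor$pigment_id,
             R = R, kappa_sq = k2, rate = rate,
             lifetime = ifelse(rate > 0, 1 / rate, Inf),
             stringsAsFactors = FALSE)
}

edgeCategory <- function(sub, chain_a, chain_b) {
  cat <- rep("other", length(chain_a))
  same <- chain_a == chain_b
  cat[same] <- "intra_subunit"
  ia <- match(chain_a, sub$chain_id); ib <- match(chain_b, sub$chain_id)
  ra <- sub$role[ia]; rb <- sub$role[ib]
  ga <- sub$ring[ia]; gb <- sub$ring[ib]
  isia2 <- !same & ra == "isia" & rb == "isia"
  cat[isia2 & ga == gb] <- "intra_ring"
  cat[isia2 & ga != gb & ga != "none" & gb != "none"] <- "inner_outer"
  core_a <- isCoreRole(ra); core_b <- isCoreRole(rb)
  cat[!same & ((core_a & rb == "isia") | (core_b & ra == "isia"))] <-
    "antenna_core"
  cat
}

#' Build the excitation-energy-transfer network
#'
#' Nodes are chlorophylls; undirected edges connect pairs within the geometric
#' Mg-Mg cutoff (or all pairs with \code{all_pairs = TRUE} for diagnostics)
#' and carry R, kappa^2, rate and lifetime, plus a category label
#' (intra-subunit, intra-ring, inner/outer interface, antenna-core, other).
#' Edge weight equals the rate. With a single Chl a spectral constant the rate
#' is donor/acceptor symmetric, so each pair is stored once.
#'
#' @param model a \code{ComplexModel} (ring assignment recommended for
#'   meaningful categories).
#' @param params \code{\link{FretParameters}}.
#' @param geometry \code{\link{GeometryThresholds}} supplying the pair cutoff.
#' @param frame optional \code{MembraneFrame}: when given, nodes carry a
#'   \code{side} attribute.
#' @param all_pairs compute the full dense pair set instead of applying the
#'   geometric cutoff.
#' @return an \pkg{igraph} undirected graph.
#' @export
buildNetwork <- function(model, params = FretParameters(),
                         geometry = GeometryThresholds(), frame = NULL,
                         all_pairs = FALSE) {
  p <- pigments(model)
  chl <- p[p$pigment_class == "chlorophyll_a", , drop = FALSE]
  s <- subunits(model)
  idx <- match(chl$chain_id, s$chain_id)
  side <- rep(NA_character_, nrow(chl))
  if (!is.null(frame) && nrow(chl)) {
    cls <- classifySidedness(model, frame)
    side <- cls$labels$side[match(chl$pigment_id, cls$labels$pigment_id)]
  }
  g <- igraph::make_empty_graph(n = nrow(chl), directed = FALSE)
  if (nrow(chl)) {
    g <- igraph::set_vertex_attr(g, "name", value = chl$pigment_id)
    g <- igraph::set_vertex_attr(g, "chain", value = chl$chain_id)
    g <- igraph::set_vertex_attr(g, "chl_number", value = chl$residue_number)
    g <- igraph::set_vertex_attr(g, "ring", value = s$ring[idx])
    g <- igraph::set_vertex_attr(g, "role", value = s$role[idx])
    g <- igraph::set_vertex_attr(g, "side", value = side)
  }
  if (nrow(chl) < 2) return(g)
  xyz <- as.matrix(chl[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  keep <- upper.tri(d) & (if (all_pairs) TRUE else d <= geometry@pairCutoff)
  sel <- which(keep, arr.ind = TRUE)
  if (!nrow(sel)) return(g)
  i <- sel[, 1]; j <- sel[, 2]
  dip <- transitionDipoles(chl)
  u <- as.matrix(dip[, c("ux", "uy", "uz")])
  rvec <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  k2 <- kappaSquared(u[i, , drop = FALSE], u[j, , drop = FALSE], rvec)
  R <- d[cbind(i, j)]
  rate <- params@C * k2 / (params@n^4 * (R / 10)^6)
  lifetime <- ifelse(rate > 0, 1 / rate, Inf)
  cat <- edgeCategory(s, chl$chain_id[i], chl$chain_id[j])
  g <- igraph::add_edges(g, rbind(i, j))
  g <- igraph::set_edge_attr(g, "R", value = R)
  g <- igraph::set_edge_attr(g, "kappa_sq", value = k2)
  g <- igraph::set_edge_attr(g, "rate", value = rate)
  g <- igraph::set_edge_attr(g, "lifetime", value = lifetime)
  g <- igraph::set_edge_attr(g, "category", value = cat)
  g <- igraph::set_edge_attr(g, "weight", value = rate)
  g
}

#' Filter a network by pairwise lifetime
#'
#' Keeps edges with lifetime strictly under \code{lifetime_max} ps (the
#' display convention: pathways with lifetime < 40 ps are drawn, >= 40 ps
#' omitted).
#'
#' @param graph an EET graph from \code{\link{buildNetwork}}.
#' @param lifetime_max ps.
#' @return the filtered graph (all nodes retained).
#' @export
filterByLifetime <- function(graph, lifetime_max = 40) {
  lt <- igraph::edge_attr(graph, "lifetime")
  igraph::delete_edges(graph, igraph::E(graph)[lt >= lifetime_max])
}

#' Ranked table of outer-to-inner antenna transfer edges
#'
#' Extracts the inner/outer interface edges, orients each as outer donor to
#' inner acceptor, and ranks them by rate (fastest first). A per-subunit-pair
#' summary reports the fastest edge and the number of fast pathways (lifetime
#' strictly under \code{fast_lifetime_max}).
#'
#' @param graph an EET graph built on a ring-assigned model.
#' @param fast_lifetime_max ps, default 20.
#' @return list with \code{edges} (data.frame: donor/acceptor pigment ids and
#'   chlorophyll numbers, subunit pair, R, kappa_sq, rate, lifetime) and
#'   \code{subunit_summary}.
#' @export
outerToInnerTable <- function(graph, fast_lifetime_max = 20) {
  empty <- list(
    edges = data.frame(donor = character(), acceptor = character(),
                       donor_chl = integer(), acceptor_chl = integer(),
                       donor_subunit = character(),
                       acceptor_subunit = character(), R = numeric(),
                       kappa_sq = numeric(), rate = numeric(),
                       lifetime = numeric(), stringsAsFactors = FALSE),
    subunit_summary = data.frame(donor_subunit = character(),
                                 acceptor_subunit = character(),
                                 fastest_lifetime = numeric(),
                                 n_fast = integer(), stringsAsFactors = FALSE))
  if (!igraph::ecount(graph)) return(empty)
  cat <- igraph::edge_attr(graph, "category")
  sel <- which(cat == "inner_outer")
  if (!length(sel)) return(empty)
  ends <- igraph::ends(graph, sel, names = FALSE)
  ring <- igraph::vertex_attr(graph, "ring")
  ## orient: donor on the outer ring, acceptor on the inner
  swap <- ring[ends[, 1]] != "outer"
  don <- ifelse(swap, ends[, 2], ends[, 1])
  acc <- ifelse(swap, ends[, 1], ends[, 2])
  nm <- igraph::vertex_attr(graph, "name")
  num <- igraph::vertex_attr(graph, "chl_number")
  ch <- igraph::vertex_attr(graph, "chain")
  edges <- data.frame(
    donor = nm[don], acceptor = nm[acc],
    donor_chl = num[don], acceptor_chl = num[acc],
    donor_subunit = ch[don], acceptor_subunit = ch[acc],
    R = igraph::edge_attr(graph, "R")[sel],
    kappa_sq = igraph::edge_attr(graph, "kappa_sq")[sel],
    rate = igraph::edge_attr(graph, "rate")[sel],
    lifetime = igraph::edge_attr(graph, "lifetime")[sel],
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$rate), , drop = FALSE]
  rownames(edges) <- NULL
  key <- paste(edges$donor_subunit, edges$acceptor_subunit)
  summ <- do.call(rbind, lapply(split(edges, key), function(e) {
    data.frame(donor_subunit = e$donor_subunit[1],
               acceptor_subunit = e$acceptor_subunit[1],
               fastest_lifetime = min(e$lifetime),
               n_fast = sum(e$lifetime < fast_lifetime_max),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$fastest_lifetime), , drop = FALSE]
  rownames(summ) <- NULL
  list(edges = edges, subunit_summary = summ)
}

## ---- export / import -------------------------------------------------------

#' Export / import an EET graph
#'
#' Supported formats: \code{"graphml"} (via \pkg{igraph}), \code{"gexf"}
#' (minimal writer/reader, suitable for Gephi), and \code{"tsv"} (edge list
#' with attributes). Re-import reproduces node ids, edge endpoints and edge
#' weights to write precision.
#'
#' @param graph an EET graph.
#' @param path output file.
#' @param format one of \code{"graphml"}, \code{"gexf"}, \code{"tsv"}.
#' @return \code{exportGraph}: the path, invisibly. \code{importGraph}: an
#'   igraph graph.
#' @export
exportGraph <- function(graph, path, format = c("graphml", "gexf", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "tsv") {
    if (igraph::ecount(graph)) {
      ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
      df <- data.frame(source = ends[, 1], target = ends[, 2],
                       stringsAsFactors = FALSE)
      for (a in igraph::edge_attr_names(graph))
        df[[a]] <- igraph::edge_attr(graph, a)
    } else {
      df <- data.frame(source = character(), target = character())
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeGexf(graph, path)
  }
  invisible(path)
}

#' @rdname exportGraph
#' @export
importGraph <- function(path, format = c("graphml", "gexf", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    verts <- unique(c(df$source, df$target))
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = data.frame(name = verts))
    return(g)
  }
  readGexf(path)
}

writeGexf <- function(graph, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://gexf.net/1.3", version = "1.3")
  gr <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  nodes <- xml2::xml_add_child(gr, "nodes")
  nm <- igraph::vertex_attr(graph, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  for (v in nm)
    xml2::xml_add_child(nodes, "node", id = v, label = v)
  edges <- xml2::xml_add_child(gr, "edges")
  if (igraph::ecount(graph)) {
    ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
    w <- igraph::edge_attr(graph, "weight")
    if (is.null(w)) w <- rep(1, nrow(ends))
    for (k in seq_len(nrow(ends)))
      xml2::xml_add_child(edges, "edge", id = as.character(k - 1),
                          source = ends[k, 1], target = ends[k, 2],
                          weight = format(w[k], digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

readGexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  eds <- xml2::xml_find_all(doc, ".//g:edge", ns)
  if (length(eds)) {
    src <- match(xml2::xml_attr(eds, "source"), ids)
    tgt <- match(xml2::xml_attr(eds, "target"), ids)
    g <- igraph::add_edges(g, rbind(src, tgt))
    g <- igraph::set_edge_attr(g, "weight",
                               value = as.numeric(xml2::xml_attr(eds, "weight")))
  }
  g
}
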