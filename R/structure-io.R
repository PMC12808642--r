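#' Residue-name and chain-role configuration for parsing
#'
#' Deposited models differ in ligand codes and chain labelling, so pigment
#' classes and subunit roles are declared rather than guessed. Chlorophyll a
#' defaults to ligand code \code{CLA}; the carotenoid set defaults to
#' \code{BCR} and can be extended (e.g. zeaxanthin-type codes).
#'
#' @param chlorophyll character vector of chlorophyll-a residue codes.
#' @param carotenoids character vector of carotenoid residue codes.
#' @param chain_roles named character vector mapping chain ids to roles
#'   (\code{"PsaA"}-style core subunit names, \code{"isia"}, \code{"other"}).
#'   Unmapped chains become \code{"other"}.
#' @param reference_chain optional chain id used as the angular reference when
#'   assigning ring indices (defaults to the antenna subunit on the PsaK pole).
#' @param on_missing_dipole \code{"error"} (default) or
#'   \code{"skip"}: what to do with a chlorophyll lacking its MG, NB or ND
#'   atom (skipping warns, never silently drops).
#' @return a list of class \code{"namingConfig"}.
#' @export
namingConfig <- function(chlorophyll = "CLA", carotenoids = "BCR",
                         chain_roles = character(),
                         reference_chain = NA_character_,
                         on_missing_dipole = c("error", "skip")) {
  on_missing_dipole <- match.arg(on_missing_dipole)
  stopifnot(is.character(chlorophyll), length(chlorophyll) >= 1)
  structure(list(chlorophyll = chlorophyll, carotenoids = carotenoids,
                 chain_roles = chain_roles,
                 reference_chain = reference_chain,
                 on_missing_dipole = on_missing_dipole),
            class = "namingConfig")
}

## ---- raw atom tables -------------------------------------------------------

parsePdbAtoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines))
    return(emptyAtoms())
  bad <- nchar(lines) < 54
  if (any(bad))
    stop("truncated PDB ATOM record at line: ",
         substr(lines[which(bad)[1]], 1, 30))
  alt <- substr(lines, 17, 17)
  if (any(!alt %in% c(" ", "A"))) {
    warning("multiple conformers present; keeping the first (altLoc ' '/'A')")
  }
  keep2 <- alt %in% c(" ", "A")
  lines <- lines[keep2]
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop("unparseable coordinate field in PDB record: ",
           substr(lines[which(is.na(v))[1]], 1, 54))
    v
  }
  data.frame(
    chain_id = trimws(substr(lines, 22, 22)),
    residue_name = trimws(substr(lines, 18, 20)),
    residue_number = as.integer(trimws(substr(lines, 23, 26))),
    atom_name = trimws(substr(lines, 13, 16)),
    x = num(substr(lines, 31, 38)),
    y = num(substr(lines, 39, 46)),
    z = num(substr(lines, 47, 54)),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
}

parseCifAtoms <- function(lines) {
  ## locate the _atom_site loop
  is_field <- startsWith(trimws(lines), "_atom_site.")
  if (!any(is_field))
    stop("no _atom_site loop found; file is not a coordinate mmCIF")
  f0 <- which(is_field)[1]
  fields <- character()
  i <- f0
  while (i <= length(lines) && startsWith(trimws(lines[i]), "_atom_site.")) {
    fields <- c(fields, sub("^_atom_site\\.", "", trimws(lines[i])))
    i <- i + 1
  }
  rows <- character()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        ln == "loop_" || startsWith(ln, "data_")) break
    rows <- c(rows, ln)
    i <- i + 1
  }
  if (!length(rows))
    stop("empty _atom_site loop")
  toks <- scan(text = paste(rows, collapse = "\n"), what = character(),
               quiet = TRUE, quote = "\"'")
  if (length(toks) %% length(fields) != 0)
    stop("malformed _atom_site loop: token count is not a multiple of the ",
         length(fields), " declared fields")
  m <- matrix(toks, ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  grp <- pick("group_PDB")
  if (!all(is.na(grp))) m <- m[grp %in% c("ATOM", "HETATM"), , drop = FALSE]
  alt <- pick("label_alt_id")
  if (!all(is.na(alt)) && any(!alt %in% c(".", "A", "?"))) {
    warning("multiple conformers present; keeping the first (alt '.'/'A')")
    m <- m[alt %in% c(".", "A", "?"), , drop = FALSE]
  }
  pick <- function(...) {   # rebind over the filtered matrix
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) stop("unparseable ", what, " in _atom_site loop")
    out
  }
  data.frame(
    chain_id = pick("auth_asym_id", "label_asym_id"),
    residue_name = pick("label_comp_id", "auth_comp_id"),
    residue_number = as.integer(suppressWarnings(
      as.numeric(pick("auth_seq_id", "label_seq_id")))),
    atom_name = gsub('"', "", pick("label_atom_id", "auth_atom_id")),
    x = num(pick("Cartn_x"), "Cartn_x"),
    y = num(pick("Cartn_y"), "Cartn_y"),
    z = num(pick("Cartn_z"), "Cartn_z"),
    element = pick("type_symbol"),
    stringsAsFactors = FALSE)
}

## ---- model assembly --------------------------------------------------------

modelFromAtoms <- function(atom_table, naming, name) {
  at <- atom_table
  pig_codes <- c(naming$chlorophyll, naming$carotenoids)
  is_pig <- at$residue_name %in% pig_codes
  key <- paste(at$chain_id, at$residue_number, at$residue_name, sep = ":")

  pigments <- emptyPigments()
  if (any(is_pig)) {
    pa <- at[is_pig, , drop = FALSE]
    pkey <- key[is_pig]
    ids <- unique(pkey)
    first <- pa[match(ids, pkey), , drop = FALSE]
    cls <- ifelse(first$residue_name %in% naming$chlorophyll,
                  "chlorophyll_a", "carotenoid")
    getAtom <- function(nm) {
      sel <- match(paste(ids, nm), paste(pkey, pa$atom_name))
      cbind(pa$x[sel], pa$y[sel], pa$z[sel])
    }
    mg <- getAtom("MG"); nb <- getAtom("NB"); nd <- getAtom("ND")
    ## carotenoid representative point: centroid of its atoms
    cen <- t(vapply(ids, function(id) {
      sub <- pa[pkey == id, , drop = FALSE]
      c(mean(sub$x), mean(sub$y), mean(sub$z))
    }, numeric(3)))
    pos <- mg
    pos[cls == "carotenoid", ] <- cen[cls == "carotenoid", ]
    missing_chl <- cls == "chlorophyll_a" &
      (is.na(mg[, 1]) | is.na(nb[, 1]) | is.na(nd[, 1]))
    if (any(missing_chl)) {
      if (naming$on_missing_dipole == "error")
        stop("chlorophyll records missing MG/NB/ND atoms: ",
             paste(ids[missing_chl], collapse = ", "))
      warning("skipping chlorophylls missing MG/NB/ND atoms: ",
              paste(ids[missing_chl], collapse = ", "))
    }
    keep <- !missing_chl
    pigments <- data.frame(
      pigment_id = ids[keep], chain_id = first$chain_id[keep],
      residue_number = first$residue_number[keep],
      residue_name = first$residue_name[keep], pigment_class = cls[keep],
      x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
      nb_x = nb[keep, 1], nb_y = nb[keep, 2], nb_z = nb[keep, 3],
      nd_x = nd[keep, 1], nd_y = nd[keep, 2], nd_z = nd[keep, 3],
      stringsAsFactors = FALSE)
  }

  ca <- at[!is_pig & at$atom_name == "CA", , drop = FALSE]
  chains <- unique(at$chain_id)
  roles <- naming$chain_roles[chains]
  roles[is.na(roles)] <- "other"
  subs <- data.frame(chain_id = chains, role = unname(roles),
                     ring = "none", ring_index = NA_integer_,
                     stringsAsFactors = FALSE)
  model <- ComplexModel(name, subs, pigments, ca)
  message(sprintf(
    "parsed %s: %d chains, %d Chl a, %d carotenoids, %d C-alpha atoms",
    name, nrow(subs), sum(pigments$pigment_class == "chlorophyll_a"),
    sum(pigments$pigment_class == "carotenoid"), nrow(ca)))
  model
}

#' Parse an atomic model into a ComplexModel
#'
#' Reads an mmCIF or PDB coordinate file, extracts chlorophyll (Mg/NB/ND) and
#' carotenoid (centroid) records, retains protein C-alpha atoms, and assigns
#' subunit roles from the naming configuration. A short parse report is
#' emitted as a message.
#'
#' @param path path to a coordinate file.
#' @param format \code{"auto"} (by extension), \code{"mmcif"} or \code{"pdb"}.
#' @param naming a \code{\link{namingConfig}}.
#' @param name model name; defaults to the file base name.
#' @return a \code{\linkS4class{ComplexModel}}.
#' @export
parseStructure <- function(path, format = c("auto", "mmcif", "pdb"),
                           naming = namingConfig(), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.(cif|pdb|ent)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("empty structure file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE) ||
                  any(startsWith(trimws(lines[seq_len(min(5, length(lines)))]),
                                 "data_")))
      "mmcif" else "pdb"
  }
  at <- if (format == "mmcif") parseCifAtoms(lines) else parsePdbAtoms(lines)
  if (!nrow(at)) stop("no atom records found in ", path)
  modelFromAtoms(at, naming, name)
}

#' Pigment census by role and ring
#'
#' Counts pigments per class, partitioned by subunit role and ring. The totals
#' over all partitions equal the number of matching pigment records.
#'
#' @param model a \code{ComplexModel}.
#' @param restrict_to optional character vector of roles to keep (e.g.
#'   \code{"isia"}); \code{NULL} keeps everything.
#' @return data.frame with columns \code{role}, \code{ring},
#'   \code{pigment_class}, \code{count} (zero rows when nothing matches).
#' @export
pigmentCensus <- function(model, restrict_to = NULL) {
  p <- pigments(model)
  s <- subunits(model)
  if (!nrow(p))
    return(data.frame(role = character(), ring = character(),
                      pigment_class = character(), count = integer(),
                      stringsAsFactors = FALSE))
  idx <- match(p$chain_id, s$chain_id)
  tab <- data.frame(role = s$role[idx], ring = s$ring[idx],
                    pigment_class = p$pigment_class, stringsAsFactors = FALSE)
  if (!is.null(restrict_to)) tab <- tab[tab$role %in% restrict_to, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(role = character(), ring = character(),
                      pigment_class = character(), count = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(count = rep(1L, nrow(tab))),
                          by = tab[c("role", "ring", "pigment_class")], FUN = sum)
  agg <- agg[order(agg$role, agg$ring, agg$pigment_class), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

PIGMENT_TABLE_COLS <- c("pigment_id", "chain_id", "residue_number",
                        "residue_name", "pigment_class", "role", "ring",
                        "ring_index", "x", "y", "z",
                        "nb_x", "nb_y", "nb_z", "nd_x", "nd_y", "nd_z")

#' Write / read the pigment table
#'
#' One row per pigment with identity, class, subunit role/ring and
#' coordinates, as a tab-separated file with a fixed column order. The
#' read-back reproduces the records to write precision.
#'
#' @param model a \code{ComplexModel}.
#' @param path output TSV path.
#' @return \code{writePigmentTable} returns the path invisibly;
#'   \code{readPigmentTable} the data.frame.
#' @export
writePigmentTable <- function(model, path) {
  p <- pigments(model)
  s <- subunits(model)
  idx <- match(p$chain_id, s$chain_id)
  out <- cbind(p[, c("pigment_id", "chain_id", "residue_number",
                     "residue_name", "pigment_class")],
               data.frame(role = s$role[idx], ring = s$ring[idx],
                          ring_index = s$ring_index[idx]),
               p[, c("x", "y", "z", "nb_x", "nb_y", "nb_z",
                     "nd_x", "nd_y", "nd_z")])
  if (!nrow(p)) {
    out <- as.data.frame(setNames(
      rep(list(character(0)), length(PIGMENT_TABLE_COLS)), PIGMENT_TABLE_COLS))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePigmentTable
#' @export
readPigmentTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
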