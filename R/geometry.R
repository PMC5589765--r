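## ---- heme-pocket geometry from PDB structures ----------------------------

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

#' Geometry targets for a synthetic heme-pocket fixture
#'
#' @param dFe_O Fe to proximal ligand oxygen O1 distance, A.
#' @param dO_O O1--O2 bond length, A.
#' @param dFe_NHis Fe to proximal-histidine NE2 distance, A.
#' @param hf8_rot proximal-imidazole rotation about the heme normal,
#'   degrees from the eclipsed conformation.
#' @param dHE7H_O1,dHE7H_O2 distal-histidine NE2-bound hydrogen to the two
#'   ligand oxygens, A.
#' @param dHF8Hd_LeuCO proximal-histidine ND1-bound hydrogen to the
#'   adjacent leucine backbone carbonyl oxygen, A.
#' @param has_ligand include the O2 ligand (and distal H-bond geometry).
#' @param chain chain identifier.
#' @return List of class `pocket_spec`.
#' @export
pocket_spec <- function(dFe_O = 1.77, dO_O = 1.30, dFe_NHis = 2.20,
                        hf8_rot = 0, dHE7H_O1 = 2.43, dHE7H_O2 = 1.83,
                        dHF8Hd_LeuCO = 1.77, has_ligand = TRUE,
                        chain = "A") {
  stopifnot(dFe_O > 0, dO_O > 0, dFe_NHis > 0, dHE7H_O1 > 0,
            dHE7H_O2 > 0, dHF8Hd_LeuCO > 0)
  if (has_ligand && abs(dHE7H_O1 - dHE7H_O2) >= dO_O)
    stop("geometrically infeasible: |dHE7H_O1 - dHE7H_O2| must be < dO_O")
  structure(as.list(environment()), class = "pocket_spec")
}

## Regular-pentagon imidazole ring in the plane spanned by (u, w), with the
## first vertex at `top` and the ring body extending along -w.
imidazole_ring <- function(top, u, w, bond = 1.37) {
  R5 <- bond / (2 * sin(pi / 5))
  ctr <- top - R5 * w
  ang <- (90 + 72 * 0:4) * pi / 180
  verts <- lapply(ang, function(a) ctr + R5 * (cos(a) * u + sin(a) * w))
  ## vertex order from the top, going around: NE2, CD2, CG, ND1, CE1
  list(NE2 = verts[[1]], CE1 = verts[[2]], ND1 = verts[[3]],
       CG = verts[[4]], CD2 = verts[[5]], center = ctr)
}

#' Write a minimal heme-pocket PDB fixture
#'
#' Builds a synthetic structure — heme iron with its four pyrrole
#' nitrogens in the z = 0 plane, proximal histidine imidazole below, ligand
#' and distal histidine imidazole above — that realizes the requested
#' geometry targets exactly (distances to 0.01 A, the rotation angle to
#' 0.5 degrees). Residues: HEM (HETATM), OXY ligand (HETATM), proximal HIS
#' 87 with HD1, distal HIS 58 with HE2, and the LEU 83 backbone carbonyl
#' oxygen accepting the proximal ND1--H bond.
#'
#' @param spec a [pocket_spec()].
#' @param path output PDB file path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(spec, path) {
  stopifnot(inherits(spec, "pocket_spec"))
  ex <- unitv(c(1, 0, 0)); ez <- unitv(c(0, 0, 1))
  atoms <- list()  # name, resid, resno, type, xyz
  add <- function(name, resid, resno, type, xyz)
    atoms[[length(atoms) + 1]] <<- list(name = name, resid = resid,
                                        resno = resno, type = type,
                                        xyz = xyz)
  ## heme: Fe at origin, pyrrole N along +-x, +-y
  add("FE", "HEM", 142, "HETATM", c(0, 0, 0))
  dFeN <- 2.05
  add("NA", "HEM", 142, "HETATM", c(dFeN, 0, 0))
  add("NB", "HEM", 142, "HETATM", c(0, dFeN, 0))
  add("NC", "HEM", 142, "HETATM", c(-dFeN, 0, 0))
  add("ND", "HEM", 142, "HETATM", c(0, -dFeN, 0))

  ## proximal His below the plane; ring plane contains the z axis and the
  ## in-plane direction u(theta); theta = 0 is eclipsed (aligned with Fe-NA)
  th <- spec$hf8_rot * pi / 180
  u <- c(cos(th), sin(th), 0)
  ne2p <- c(0, 0, -spec$dFe_NHis)
  ringp <- imidazole_ring(ne2p, u, ez)  # w = +z: ring extends below NE2
  for (nm in c("NE2", "CE1", "ND1", "CG", "CD2"))
    add(nm, "HIS", 87, "ATOM", ringp[[nm]])
  ## CB off CG, away from ring center, slightly out of plane for realism
  cb <- ringp$CG + 1.52 * unitv(ringp$CG - ringp$center)
  add("CB", "HIS", 87, "ATOM", cb)
  ## ND1-H pointing outward from the ring center
  hd1_dir <- unitv(ringp$ND1 - ringp$center)
  hd1 <- ringp$ND1 + 1.01 * hd1_dir
  add("HD1", "HIS", 87, "ATOM", hd1)
  ## leucine backbone carbonyl O along the H-bond axis
  add("O", "LEU", 83, "ATOM", hd1 + spec$dHF8Hd_LeuCO * hd1_dir)
  add("C", "LEU", 83, "ATOM",
      hd1 + (spec$dHF8Hd_LeuCO + 1.23) * hd1_dir)

  if (spec$has_ligand) {
    o1 <- c(0, 0, spec$dFe_O)
    tilt <- 60 * pi / 180   # bent end-on Fe-O-O geometry
    o2 <- o1 + spec$dO_O * c(sin(tilt), 0, cos(tilt))
    add("O1", "OXY", 143, "HETATM", o1)
    add("O2", "OXY", 143, "HETATM", o2)
    ## distal-His H at the two spec'd H...O distances (sphere intersection)
    e <- unitv(o2 - o1)
    L <- spec$dO_O
    t <- (spec$dHE7H_O1^2 - spec$dHE7H_O2^2 + L^2) / (2 * L)
    rho2 <- spec$dHE7H_O1^2 - t^2
    if (rho2 < 0)
      stop("geometrically infeasible distal H...O1/O2 distances")
    rhat <- unitv(pracma_cross(e, c(0, 1, 0)))
    he2 <- o1 + t * e + sqrt(rho2) * rhat
    add("HE2", "HIS", 58, "ATOM", he2)
    ## distal NE2 extends away from the ligand midpoint
    dhat <- unitv(he2 - 0.5 * (o1 + o2))
    ne2d <- he2 + 1.01 * dhat
    wd <- dhat
    ud <- unitv(pracma_cross(wd, c(0, 0, 1)))
    ringd <- imidazole_ring(ne2d, ud, -wd)  # ring extends away from ligand
    for (nm in c("NE2", "CE1", "ND1", "CG", "CD2"))
      add(nm, "HIS", 58, "ATOM", ringd[[nm]])
  }

  xyz <- unlist(lapply(atoms, `[[`, "xyz"))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = vapply(atoms, `[[`, character(1), "type"),
    resno = vapply(atoms, `[[`, numeric(1), "resno"),
    resid = vapply(atoms, `[[`, character(1), "resid"),
    elety = vapply(atoms, `[[`, character(1), "name"),
    chain = rep(spec$chain, length(atoms)),
    o = rep(1, length(atoms)), b = rep(0, length(atoms)))
  invisible(path)
}

## cross product (avoid pulling in a package for one line)
pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Read a PDB structure into an atom table
#'
#' Thin wrapper over [bio3d::read.pdb()]: keeps the highest-occupancy
#' alternate location per atom and returns a queryable atom table.
#'
#' @param pdb_path path to a PDB file.
#' @return Object of class `structure_model` (data frame of atoms plus the
#'   source path).
#' @export
read_structure <- function(pdb_path) {
  if (!file.exists(pdb_path)) stop("no such file: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  ## resolve altlocs: keep the highest occupancy per (chain, resno, elety)
  key <- paste(at$chain, at$resno, at$resid, at$elety)
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx)
      idx[which.max(at$o[idx])]))
    at <- at[sort(keep), ]
  }
  structure(list(atoms = at, path = pdb_path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model: %d atoms, %d chain(s), from %s>\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              basename(x$path)))
  invisible(x)
}

## coordinates of one named atom; error names every missing atom
get_xyz <- function(model, chain, resid, elety, resno = NULL) {
  at <- model$atoms
  sel <- at$chain == chain & at$resid == resid & at$elety == elety
  if (!is.null(resno)) sel <- sel & at$resno == resno
  i <- which(sel)
  if (length(i) == 0)
    stop("missing atom: ", elety, " of ", resid,
         if (!is.null(resno)) paste0(" ", resno), " in chain ", chain)
  as.numeric(at[i[1], c("x", "y", "z")])
}

## least-squares plane of points (rows); returns list(center, normal)
ls_plane <- function(P) {
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

#' Heme-pocket geometric descriptors
#'
#' Computes the standard pocket geometry of one subunit: Fe--O1 and O1--O2
#' distances, the Fe to proximal-His NE2 distance, the proximal-imidazole
#' rotation angle, the distal-His H to ligand-O distances, and the
#' proximal ND1--H to leucine carbonyl distance. The rotation angle is
#' operationalized as the angle between the projection of the proximal
#' imidazole NE2 to ND1 axis onto the porphyrin mean plane (least-squares
#' plane of the four pyrrole nitrogens) and the nearest Fe to pyrrole-N
#' direction, folded into `[0, 45]` degrees by the porphyrin's four-fold
#' pseudo-symmetry (0 = eclipsed). The iron's out-of-plane displacement is
#' reported as a bonus descriptor.
#'
#' @param model a [read_structure()] result.
#' @param chain chain identifier.
#' @param has_ligand compute ligand and distal H-bond metrics.
#' @param labels optional `list(subunit=, state=)` labels.
#' @return List of class `pocket_descriptors`.
#' @export
pocket_descriptors <- function(model, chain = "A", has_ligand = TRUE,
                               labels = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  fe <- get_xyz(model, chain, "HEM", "FE")
  Np <- rbind(get_xyz(model, chain, "HEM", "NA"),
              get_xyz(model, chain, "HEM", "NB"),
              get_xyz(model, chain, "HEM", "NC"),
              get_xyz(model, chain, "HEM", "ND"))
  plane <- ls_plane(Np)

  ## identify proximal (NE2 nearest Fe) and distal histidines
  his <- unique(at$resno[at$chain == chain & at$resid == "HIS" &
                         at$elety == "NE2"])
  if (length(his) == 0) stop("missing atom: NE2 of HIS in chain ", chain)
  dfe <- vapply(his, function(rn)
    vnorm(get_xyz(model, chain, "HIS", "NE2", rn) - fe), numeric(1))
  prox_rn <- his[which.min(dfe)]
  dist_rn <- if (length(his) > 1) his[order(dfe)][2] else NA

  ne2p <- get_xyz(model, chain, "HIS", "NE2", prox_rn)
  nd1p <- get_xyz(model, chain, "HIS", "ND1", prox_rn)
  dFe_NHis <- vnorm(ne2p - fe)

  ## rotation angle: in-plane projection of the imidazole axis vs the
  ## nearest Fe->N_pyrrole direction
  proj <- function(v) v - sum(v * plane$normal) * plane$normal
  vax <- proj(nd1p - ne2p)
  ang_to <- function(a, b)
    acos(pmin(1, pmax(-1, sum(unitv(a) * unitv(b))))) * 180 / pi
  angles <- apply(Np, 1, function(np) ang_to(vax, proj(np - fe)))
  hf8_rot <- min(angles)

  ## proximal ND1-H to leucine carbonyl
  dHF8Hd_LeuCO <- NA_real_
  hd1 <- tryCatch(get_xyz(model, chain, "HIS", "HD1", prox_rn),
                  error = function(e) NULL)
  leu_o <- at[at$chain == chain & at$resid == "LEU" & at$elety == "O", ]
  if (!is.null(hd1) && nrow(leu_o) > 0) {
    d <- sqrt((leu_o$x - hd1[1])^2 + (leu_o$y - hd1[2])^2 +
              (leu_o$z - hd1[3])^2)
    dHF8Hd_LeuCO <- min(d)
  }

  dFe_O <- dO_O <- dHE7H_O1 <- dHE7H_O2 <- NA_real_
  if (has_ligand) {
    o1 <- get_xyz(model, chain, "OXY", "O1")
    o2 <- get_xyz(model, chain, "OXY", "O2")
    dFe_O <- vnorm(o1 - fe)
    dO_O <- vnorm(o2 - o1)
    if (!is.na(dist_rn)) {
      he2 <- tryCatch(get_xyz(model, chain, "HIS", "HE2", dist_rn),
                      error = function(e) NULL)
      if (!is.null(he2)) {
        dHE7H_O1 <- vnorm(he2 - o1)
        dHE7H_O2 <- vnorm(he2 - o2)
      }
    }
  }

  structure(
    list(dFe_O = dFe_O, dO_O = dO_O, dFe_NHis = dFe_NHis,
         HF8_rot_angle = hf8_rot, dHE7H_O1 = dHE7H_O1,
         dHE7H_O2 = dHE7H_O2, dHF8Hd_LeuCO = dHF8Hd_LeuCO,
         fe_oop = abs(sum((fe - plane$center) * plane$normal)),
         labels = labels),
    class = "pocket_descriptors")
}

#' @export
print.pocket_descriptors <- function(x, ...) {
  cat("<pocket_descriptors>\n")
  for (f in c("dFe_O", "dO_O", "dFe_NHis", "HF8_rot_angle", "dHE7H_O1",
              "dHE7H_O2", "dHF8Hd_LeuCO", "fe_oop"))
    cat(sprintf("  %-14s %s\n", f,
                ifelse(is.na(x[[f]]), "NA", sprintf("%.3f", x[[f]]))))
  invisible(x)
}

#' Difference table between two descriptor sets
#'
#' Per-field differences `b - a`. Changes in the Fe to proximal-His
#' distance of at least 0.05 A are flagged as proximal-effect candidates
#' (the scale of the tense-to-relaxed alpha-subunit change).
#'
#' @param desc_a,desc_b [pocket_descriptors()] results.
#' @param proximal_threshold flag threshold on `|d dFe_NHis|`, A.
#' @return Data frame of field, value_a, value_b, delta, flag.
#' @export
compare_states <- function(desc_a, desc_b, proximal_threshold = 0.05) {
  stopifnot(inherits(desc_a, "pocket_descriptors"),
            inherits(desc_b, "pocket_descriptors"))
  fields <- c("dFe_O", "dO_O", "dFe_NHis", "HF8_rot_angle", "dHE7H_O1",
              "dHE7H_O2", "dHF8Hd_LeuCO", "fe_oop")
  va <- vapply(fields, function(f) desc_a[[f]], numeric(1))
  vb <- vapply(fields, function(f) desc_b[[f]], numeric(1))
  delta <- vb - va
  flag <- rep("", length(fields))
  flag[fields == "dFe_NHis" & !is.na(delta) &
       abs(delta) >= proximal_threshold] <- "proximal-effect candidate"
  data.frame(field = fields, value_a = va, value_b = vb, delta = delta,
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}
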