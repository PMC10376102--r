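#' Signed dihedral (torsion) angle of four points
#'
#' Computes the torsion angle about the p2--p3 axis using the IUPAC sign
#' convention: 0 degrees for the cis (eclipsed) arrangement, 180 for trans,
#' positive for a clockwise rotation of the far bond when viewed from p2
#' towards p3. The result is invariant under rigid-body motion of all four
#' points and is negated by a mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (angstrom).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)) # cis, 0
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)) # trans, 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(b1^2)) < 1e-10 || nb2 < 1e-10 || sqrt(sum(b3^2)) < 1e-10) {
    abort("dihedral undefined: consecutive points coincide",
          class = "torsionflux_degenerate_dihedral")
  }
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  if (sqrt(sum(c12^2)) < 1e-10 || sqrt(sum(c23^2)) < 1e-10) {
    abort("dihedral undefined: three consecutive points are collinear",
          class = "torsionflux_degenerate_dihedral")
  }
  x <- sum(c12 * c23)
  y <- sum(cross3(c12, c23) * b2) / nb2
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap degrees into (-180, 180]
wrap_angle <- function(theta) {
  w <- theta - 360 * floor((theta + 180) / 360)
  w[w == -180] <- 180
  w
}

#' Standard peptide backbone geometry
#'
#' Idealised bond lengths (angstrom) and bond angles (degrees) used when
#' rebuilding backbone coordinates from internal coordinates.
#'
#' @return Named list with bond lengths `n_ca`, `ca_c`, `c_n` and bond angles
#'   `n_ca_c`, `ca_c_n`, `c_n_ca`.
#' @export
peptide_geometry <- function() {
  list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
       n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7)
}

# Natural-extension placement: position atom d so that |cd| = len,
# angle(b, c, d) = ang and torsion(a, b, c, d) = tor (degrees).
place_atom <- function(a, b, c, len, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  d_local <- c(-len * cos(ang),
               len * sin(ang) * cos(tor),
               len * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- cross3(ab, bc)
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- cbind(bc, cross3(nrm, bc), nrm)
  c(m %*% d_local) + c
}

#' Build one backbone model from torsion angles
#'
#' Places N, CA and C atoms for a chain of `L` residues by sequential
#' natural-extension from idealised internal coordinates. Per-residue phi,
#' psi and omega lists must share length `L`; the first phi and last psi are
#' not used (those torsions do not exist at chain termini). Recomputing
#' dihedrals from the returned coordinates reproduces the inputs at every
#' defined position.
#'
#' @param phi,psi Numeric vectors of backbone torsions in degrees, length L.
#' @param omega Peptide-bond torsion per residue (degrees); defaults to a
#'   trans backbone (180). Recycled to length L.
#' @param geometry Bond lengths/angles, see [peptide_geometry()].
#' @return A `3L x 3` numeric matrix of coordinates, rows ordered
#'   N, CA, C per residue, with rownames like `"N_1"`, `"CA_1"`, `"C_1"`.
#' @examples
#' xyz <- build_backbone(rep(-57, 5), rep(-47, 5))
#' @export
build_backbone <- function(phi, psi, omega = 180, geometry = peptide_geometry()) {
  L <- length(phi)
  if (length(psi) != L) {
    abort("`phi` and `psi` must have equal length")
  }
  omega <- rep_len(omega, L)
  g <- geometry
  xyz <- matrix(NA_real_, nrow = 3L * L, ncol = 3L)
  rownames(xyz) <- paste0(rep(c("N", "CA", "C"), L), "_", rep(seq_len(L), each = 3))
  # first residue spans the xy-plane
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$n_ca, 0, 0)
  th <- g$n_ca_c * pi / 180
  xyz[3, ] <- xyz[2, ] + g$ca_c * c(-cos(th), sin(th), 0)
  if (L > 1) {
    for (i in 2:L) {
      nr <- 3L * (i - 1L)
      # N(i): torsion N(i-1)-CA(i-1)-C(i-1)-N(i) = psi(i-1)
      xyz[nr + 1, ] <- place_atom(xyz[nr - 2, ], xyz[nr - 1, ], xyz[nr, ],
                                  g$c_n, g$ca_c_n, psi[i - 1])
      # CA(i): torsion CA(i-1)-C(i-1)-N(i)-CA(i) = omega(i)
      xyz[nr + 2, ] <- place_atom(xyz[nr - 1, ], xyz[nr, ], xyz[nr + 1, ],
                                  g$n_ca, g$c_n_ca, omega[i])
      # C(i): torsion C(i-1)-N(i)-CA(i)-C(i) = phi(i)
      xyz[nr + 3, ] <- place_atom(xyz[nr, ], xyz[nr + 1, ], xyz[nr + 2, ],
                                  g$ca_c, g$n_ca_c, phi[i])
    }
  }
  xyz
}

#' Construct a multi-model backbone ensemble
#'
#' Container for one chain's N/CA/C coordinates across the M models of a
#' structural ensemble (e.g. an NMR deposition).
#'
#' @param chain_id Chain identifier.
#' @param sequence One-letter amino-acid string of length L ("X" marks a
#'   nonstandard residue).
#' @param models List of M coordinate matrices as returned by
#'   [build_backbone()] (`3L x 3`, rows N/CA/C per residue).
#' @param complete Logical length-L vector; FALSE flags residues whose
#'   backbone is incomplete in at least one model (excluded from labels).
#' @return An object of class `taf_ensemble`.
#' @export
taf_ensemble <- function(chain_id, sequence, models, complete = NULL) {
  L <- nchar(sequence)
  if (length(models) < 1L) abort("an ensemble needs at least one model")
  for (m in models) {
    if (!is.matrix(m) || nrow(m) != 3L * L || ncol(m) != 3L) {
      abort(sprintf("each model must be a %d x 3 coordinate matrix", 3L * L))
    }
  }
  complete <- complete %||% rep(TRUE, L)
  structure(
    list(chain_id = chain_id, sequence = sequence, models = models,
         complete = complete,
         nonstandard = grepl("X", sequence, fixed = TRUE)),
    class = "taf_ensemble"
  )
}

#' @export
print.taf_ensemble <- function(x, ...) {
  cat(sprintf("<taf_ensemble> chain %s: %d residues, %d models%s\n",
              x$chain_id, nchar(x$sequence), length(x$models),
              if (x$nonstandard) ", nonstandard residues" else ""))
  invisible(x)
}

n_models <- function(e) length(e$models)
chain_length <- function(e) nchar(e$sequence)

#' Read a multi-model PDB file into backbone ensembles
#'
#' Parses a PDB file (MODEL/ENDMDL records, or a single implicit model),
#' keeping only N, CA and C atoms. Alternate locations are resolved to the
#' highest-occupancy copy (ties: first encountered). Residues missing any
#' backbone atom are flagged incomplete; unknown residue names are kept and
#' marked nonstandard ("X") so that dataset filters can reject the chain.
#'
#' @param path Path to a PDB file.
#' @param chains Optional character vector restricting which chain ids to
#'   return; default all chains present.
#' @return A named list of [taf_ensemble()] objects, one per chain.
#' @export
read_multimodel_pdb <- function(path, chains = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  keep <- at$elety %in% c("N", "CA", "C") & at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) abort(sprintf("no backbone atoms in %s", path))
  at$row_id <- which(keep)
  # resolve altlocs: highest occupancy wins, first encountered breaks ties
  at$insert_chr <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, at$insert_chr, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(at$row_id), , drop = FALSE]

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  M <- nrow(xyz)

  chain_ids <- unique(at$chain)
  if (!is.null(chains)) chain_ids <- intersect(chain_ids, chains)
  out <- list()
  for (ch in chain_ids) {
    ca <- at[at$chain == ch, , drop = FALSE]
    # residue order: sequence number then insertion code
    res_key <- paste(ca$resno, ca$insert_chr)
    res_levels <- unique(res_key[order(ca$resno, ca$insert_chr)])
    L <- length(res_levels)
    aa3 <- vapply(res_levels, function(k) ca$resid[res_key == k][1], "")
    aa1 <- suppressWarnings(bio3d::aa321(aa3))
    aa1[is.na(aa1) | !(aa1 %in% AA_STANDARD)] <- "X"
    complete <- rep(TRUE, L)
    idx <- matrix(NA_integer_, nrow = 3L * L, ncol = 1L)
    for (i in seq_len(L)) {
      rows <- ca[res_key == res_levels[i], , drop = FALSE]
      for (j in seq_along(c("N", "CA", "C"))) {
        atom <- c("N", "CA", "C")[j]
        hit <- rows$row_id[rows$elety == atom]
        if (length(hit) == 0L) {
          complete[i] <- FALSE
        } else {
          idx[3L * (i - 1L) + j, 1L] <- hit[1]
        }
      }
    }
    if (!any(complete)) {
      warn(sprintf("chain %s rejected: no residue has a complete backbone", ch))
      next
    }
    models <- lapply(seq_len(M), function(m) {
      mat <- matrix(NA_real_, nrow = 3L * L, ncol = 3L)
      ok <- !is.na(idx[, 1L])
      cols <- rep((idx[ok, 1L] - 1L) * 3L, each = 3L) + rep(1:3, sum(ok))
      mat[ok, ] <- matrix(xyz[m, cols], ncol = 3L, byrow = TRUE)
      rownames(mat) <- paste0(rep(c("N", "CA", "C"), L), "_", rep(seq_len(L), each = 3))
      mat
    })
    out[[ch]] <- taf_ensemble(ch, paste(aa1, collapse = ""), models,
                              complete = complete)
  }
  out
}

#' Write a backbone ensemble as a multi-model PDB file
#'
#' Emits MODEL/ENDMDL blocks with fixed-column ATOM records for the N, CA
#' and C atoms, so that generated fixtures exercise the same format the
#' reader consumes.
#'
#' @param e A [taf_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(e, path) {
  aa1 <- strsplit(e$sequence, "")[[1]]
  aa3 <- ifelse(aa1 == "X", "UNK", bio3d::aa123(aa1))
  L <- length(aa1)
  atoms <- c(" N  ", " CA ", " C  ")
  elements <- c("N", "C", "C")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(e$models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- e$models[[m]]
    serial <- 0L
    for (i in seq_len(L)) {
      for (j in 1:3) {
        row <- xyz[3L * (i - 1L) + j, ]
        if (anyNA(row)) next
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, atoms[j], aa3[i], substr(e$chain_id, 1, 1), i,
          row[1], row[2], row[3], 1, 0, elements[j]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Per-model backbone dihedrals of an ensemble
#'
#' Computes phi(i) from C(i-1)-N(i)-CA(i)-C(i) and psi(i) from
#' N(i)-CA(i)-C(i)-N(i+1) for every model. Undefined positions -- chain
#' termini, residues with incomplete backbones, and degenerate geometry --
#' are returned as NA, never as silent zeros.
#'
#' @param e A [taf_ensemble()].
#' @return A tibble with columns `chain_id`, `model`, `residue_index`
#'   (0-based), `aa`, `phi`, `psi` (degrees in (-180, 180], NA where
#'   undefined).
#' @export
backbone_dihedrals <- function(e) {
  stopifnot(inherits(e, "taf_ensemble"))
  L <- chain_length(e)
  aa <- strsplit(e$sequence, "")[[1]]
  M <- n_models(e)
  res <- vector("list", M)
  safe_dihedral <- function(p1, p2, p3, p4) {
    if (anyNA(c(p1, p2, p3, p4))) return(NA_real_)
    tryCatch(dihedral_angle(p1, p2, p3, p4),
             torsionflux_degenerate_dihedral = function(e) NA_real_)
  }
  for (m in seq_len(M)) {
    xyz <- e$models[[m]]
    at <- function(i, j) xyz[3L * (i - 1L) + j, ]  # j: 1=N, 2=CA, 3=C
    phi <- rep(NA_real_, L)
    psi <- rep(NA_real_, L)
    for (i in seq_len(L)) {
      if (!e$complete[i]) next
      if (i > 1L && e$complete[i - 1L]) {
        phi[i] <- safe_dihedral(at(i - 1L, 3), at(i, 1), at(i, 2), at(i, 3))
      }
      if (i < L && e$complete[i + 1L]) {
        psi[i] <- safe_dihedral(at(i, 1), at(i, 2), at(i, 3), at(i + 1L, 1))
      }
    }
    res[[m]] <- tibble(chain_id = e$chain_id, model = m,
                       residue_index = seq_len(L) - 1L, aa = aa,
                       phi = phi, psi = psi)
  }
  bind_rows(res)
}
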