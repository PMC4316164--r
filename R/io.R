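# Readers / writers: FASTA, PDB (fixed-column, multi-model), flat
# key-value run configuration, CSV energy logs.

.AA3 <- c(A="ALA",R="ARG",N="ASN",D="ASP",C="CYS",Q="GLN",E="GLU",G="GLY",
          H="HIS",I="ILE",L="LEU",K="LYS",M="MET",F="PHE",P="PRO",S="SER",
          T="THR",W="TRP",Y="TYR",V="VAL")
.AA3rev <- setNames(names(.AA3), .AA3)

#' Read peptide sequences from FASTA
#'
#' @param path FASTA file.
#' @return named list of \linkS4class{PeptideSequence}; chains are
#'   assigned A, B, ... in record order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  out <- list()
  for (k in seq_along(ss)) {
    id <- sub("\\s.*", "", names(ss)[k])
    res <- strsplit(as.character(ss[[k]]), "")[[1]]
    bad <- which(!(res %in% AA1))
    if (length(bad))
      stop(sprintf("record '%s': illegal character '%s' at sequence position %d",
                   id, res[bad[1]], bad[1]))
    out[[id]] <- peptideSequence(id, res,
                                 chain = LETTERS[(k - 1) %% 26 + 1])
  }
  out
}

#' Write peptide sequences as FASTA (wrapped at 60 columns)
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "PeptideSequence")) seqs <- list(seqs)
  ss <- Biostrings::AAStringSet(vapply(seqs, as.character, character(1)))
  names(ss) <- vapply(seqs, function(s) s@id, character(1))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Read a PDB file into a coarse-grained system
#'
#' Maps CA atoms to backbone beads and CB atoms (when present) to
#' sidechain beads, preserving chain ids and residue numbering.
#' Residues without a CA are skipped with a warning; a gap in residue
#' numbers is reported as a chain break.
#'
#' @export
readPdb <- function(path, ff = defaultForceField()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  rows <- list(); coords <- list(); id <- 0L
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, ]
    resnos <- sort(unique(a$resno))
    if (any(diff(resnos) > 1))
      message("chain ", ch, ": residue-number gap (chain break) detected")
    for (rn in resnos) {
      res <- a[a$resno == rn, ]
      code <- .AA3rev[res$resid[1]]
      if (is.na(code)) next
      ca <- res[res$elety == "CA", ]
      if (!nrow(ca)) {
        warning("chain ", ch, " residue ", rn, ": no CA; skipped")
        next
      }
      id <- id + 1L
      rows[[length(rows) + 1L]] <-
        .particleRow(id, ch, rn, code, "backbone", ff)
      coords[[length(coords) + 1L]] <- c(ca$x[1], ca$y[1], ca$z[1])
      cb <- res[res$elety == "CB", ]
      if (nrow(cb) && code != "G") {
        id <- id + 1L
        rows[[length(rows) + 1L]] <-
          .particleRow(id, ch, rn, code, "sidechain", ff)
        coords[[length(coords) + 1L]] <- c(cb$x[1], cb$y[1], cb$z[1])
      }
    }
  }
  particles <- do.call(rbind, rows)
  coords <- do.call(rbind, coords)
  colnames(coords) <- c("x", "y", "z")

  # re-derive per-chain bead bonds from the table
  bonds <- list()
  for (ch in unique(particles$chain)) {
    bb <- which(particles$chain == ch & particles$role == "backbone")
    bb <- bb[order(particles$resIndex[bb])]
    consec <- which(diff(particles$resIndex[bb]) == 1)
    for (i in consec)
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = bb[i], j = bb[i + 1], dmin = ff$bondCACA[1],
        dmax = ff$bondCACA[2])
    gap2 <- which(particles$resIndex[bb][-(1:2)] -
                  particles$resIndex[bb][seq_len(length(bb) - 2)] == 2)
    for (i in gap2)
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = bb[i], j = bb[i + 2], dmin = ff$bondCA13[1],
        dmax = ff$bondCA13[2])
    sc <- which(particles$chain == ch & particles$role == "sidechain")
    for (s in sc) {
      b <- bb[particles$resIndex[bb] == particles$resIndex[s]]
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = b, j = s, dmin = ff$bondCASC[1], dmax = ff$bondCASC[2])
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(0), j = integer(0), dmin = numeric(0),
               dmax = numeric(0))
  .buildSystem(particles, coords, bonds, ff)
}

.pdbAtomLine <- function(serial, name, resName, chain, resSeq, xyz, b) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000, paste0(" ", name), resName, chain, resSeq,
          xyz[1], xyz[2], xyz[3], 1.00, b)
}

.writeModel <- function(con, sys, coords, bfac) {
  p <- sys@particles
  for (i in seq_len(nrow(p))) {
    name <- if (p$role[i] == "backbone") "CA" else "CB"
    writeLines(.pdbAtomLine(i, name, .AA3[[p$resCode[i]]], p$chain[i],
                            p$resIndex[i], coords[i, ], bfac[i]), con)
  }
}

#' Write a system or trajectory as fixed-column PDB
#'
#' Beads are emitted as CA/CB pseudo-atoms; a \linkS4class{Trajectory}
#' becomes a multi-MODEL file with per-frame energies in REMARK records.
#' Optional per-residue values (for example hIAPP-binding frequencies)
#' are written into the B-factor column, clamped to [0, 99.99].
#'
#' @param x \linkS4class{MolecularSystem} or \linkS4class{Trajectory}.
#' @param bfactorValues numeric, one value per residue (ordered by chain
#'   then residue) or per bead.
#' @export
writePdb <- function(x, path, bfactorValues = NULL) {
  sys <- if (is(x, "Trajectory")) x@system else x
  p <- sys@particles
  bfac <- rep(0, nrow(p))
  if (!is.null(bfactorValues)) {
    resKey <- paste(p$chain, p$resIndex)
    ures <- unique(resKey)
    if (length(bfactorValues) == length(ures)) {
      bfac <- bfactorValues[match(resKey, ures)]
    } else if (length(bfactorValues) == nrow(p)) {
      bfac <- bfactorValues
    } else {
      stop("bfactorValues must have one value per residue (",
           length(ures), ") or per bead (", nrow(p), ")")
    }
    bfac <- pmin(pmax(bfac, 0), 99.99)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (is(x, "Trajectory")) {
    for (f in seq_len(nFrames(x))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf("REMARK   3 TIME %.3f EPOT %.6f EKIN %.6f",
                         x@times[f], x@epot[f], x@ekin[f]), con)
      .writeModel(con, sys, .frameCoords(x, f), bfac)
      writeLines("ENDMDL", con)
    }
  } else {
    .writeModel(con, sys, sys@coords, bfac)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model bead PDB back into a trajectory
#' @export
readTrajectoryPdb <- function(path, sys = NULL, ff = defaultForceField()) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) stop("no MODEL records in ", path)
  ends <- grep("^ENDMDL", lines)
  if (is.null(sys)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(c(lines[(starts[1] + 1):(ends[1] - 1)], "END"), tmp)
    sys <- readPdb(tmp, ff)
    unlink(tmp)
  }
  nf <- length(starts)
  n <- nParticles(sys)
  frames <- array(NA_real_, c(nf, n, 3))
  times <- epot <- ekin <- numeric(nf)
  for (f in seq_len(nf)) {
    block <- lines[(starts[f] + 1):(ends[f] - 1)]
    rem <- grep("^REMARK   3 TIME", block, value = TRUE)
    if (length(rem)) {
      v <- as.numeric(strsplit(rem[1], "\\s+")[[1]][c(4, 6, 8)])
      times[f] <- v[1]; epot[f] <- v[2]; ekin[f] <- v[3]
    } else times[f] <- f - 1
    at <- grep("^ATOM", block, value = TRUE)
    if (length(at) != n) stop("model ", f, ": expected ", n, " beads")
    frames[f, , ] <- cbind(as.numeric(substr(at, 31, 38)),
                           as.numeric(substr(at, 39, 46)),
                           as.numeric(substr(at, 47, 54)))
  }
  new("Trajectory", times = times, frames = frames, epot = epot,
      ekin = ekin, temperature = rep(NA_real_, nf), runId = rep(1L, nf),
      system = sys, sampleInterval = if (nf > 1) diff(times[1:2]) else 1,
      finalCoords = matrix(frames[nf, , ], ncol = 3),
      finalVelocities = matrix(0, n, 3), nEvents = NA_real_)
}

#' Default run configuration
#'
#' Defaults mirror the standard protocol: production length 2e6 time
#' units (100 ns at ~50 fs per unit), 10 independent constant-T runs (20
#' for the largest systems), 8-replica exchange on [0.5, 0.675].
#' @export
defaultRunConfig <- function() {
  list(model.level = "two_bead", model.n_steps = 4,
       electrostatics.debye_length = 10, electrostatics.cutoff = 30,
       run.duration = 2e6, run.time_unit_fs = 50,
       run.n_independent = 10, run.n_independent_large = 20,
       run.temperature = 0.6, run.sample_interval = 1000,
       thermostat.ghost_rate = 0.1,
       rex.n_replicas = 8, rex.tmin = 0.5, rex.tmax = 0.675,
       rex.exchange_period = 1000, rex.acceptance_window = c(0.3, 0.7),
       analysis.contact_cutoff = 5, analysis.window_fraction = 0.5,
       analysis.cluster_k = 50, analysis.low_energy_fraction = 0.25,
       analysis.sliding_window = 3500,
       wham.tol = 1e-7, wham.max_iter = 1e5, wham.burn_in = 0.5,
       kelvin_scale = 503)
}

#' Read a flat key = value configuration file
#'
#' Unknown keys are rejected (no silent defaults); values are coerced to
#' the type of the default entry.
#' @export
readRunConfig <- function(path) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (is.numeric(cfg[[key]]))
      as.numeric(strsplit(val, ",")[[1]]) else val
  }
  cfg
}

#' Write / read a CSV energy log (t, E_pot, E_kin, T_inst)
#'
#' The header line carries the column units.
#' @export
writeEnergyLog <- function(traj, path) {
  n <- dim(traj@frames)[2]
  df <- data.frame(t_tu = traj@times, Epot_kcal_mol = traj@epot,
                   Ekin_kcal_mol = traj@ekin,
                   Tinst_reduced = 2 * traj@ekin / (3 * n))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnergyLog
#' @export
readEnergyLog <- function(path) utils::read.csv(path)

#' Write a contact map as TSV plus a per-residue frequency CSV
#' @export
writeContactMap <- function(cm, path, bindingPath = NULL) {
  m <- frequencyMatrix(cm)
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(bindingPath)) {
    utils::write.csv(data.frame(
      residue = c(seq_len(nrow(m)), seq_len(ncol(m))),
      chain = c(rep(cm@rowChain, nrow(m)), rep(cm@colChain, ncol(m))),
      binding_frequency = c(cm@rowBinding, cm@colBinding)),
      bindingPath, row.names = FALSE)
  }
  invisible(path)
}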