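#' Load a sequence from FASTA
#'
#' Reads a single- or multi-record FASTA file (via seqinr) and returns one
#' record as a \code{\link{sequence_record}}.
#'
#' @param path FASTA file path.
#' @param which Record index or name (default first).
#' @param offset Author numbering offset of the first residue.
#' @return A \code{sequence_record}.
#' @export
load_sequence <- function(path, which = 1L, offset = 1L) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("package 'seqinr' is required to read FASTA files", call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  rec <- recs[[which]]
  nm <- if (is.character(which)) which else names(recs)[which]
  sequence_record(toupper(rec), id = nm, offset = offset)
}

#' Load a conformational ensemble
#'
#' Reads coordinates into a \code{\link{traj_ensemble}} from either a
#' multi-model PDB (via bio3d; each MODEL becomes a frame, CA and backbone
#' N/O atoms are extracted, coordinates converted from Angstrom to nm) or
#' a coordinate table (CSV with columns \code{frame}, \code{residue},
#' \code{x}, \code{y}, \code{z}, already in nm; optionally \code{atom}
#' with values "CA", "N", "O").
#'
#' @param path File path (.pdb or .csv by extension).
#' @param format "auto", "pdb" or "csv".
#' @return A \code{traj_ensemble}.
#' @export
load_trajectory <- function(path, format = c("auto", "pdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "csv"
  }
  if (format == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("package 'bio3d' is required to read PDB files", call. = FALSE)
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    at <- pdb$atom
    resids <- sort(unique(at$resno[at$elety == "CA"]))
    nr <- length(resids)
    xyz <- pdb$xyz
    nf <- nrow(xyz)
    pull <- function(elety) {
      sel <- which(at$elety == elety & at$resno %in% resids)
      if (length(sel) != nr) return(NULL)
      sel <- sel[match(resids, at$resno[sel])]
      arr <- array(NA_real_, c(nf, nr, 3L))
      for (a in 1:3) arr[, , a] <- xyz[, 3L * (sel - 1L) + a, drop = FALSE]
      arr / 10 # Angstrom (PDB convention) -> nm
    }
    ca <- pull("CA")
    if (is.null(ca)) stop("PDB lacks one CA per residue", call. = FALSE)
    traj_ensemble(ca, n_atoms = pull("N"), o_atoms = pull("O"))
  } else {
    tab <- read.csv(path)
    need <- c("frame", "residue", "x", "y", "z")
    if (!all(need %in% names(tab))) {
      stop("coordinate table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(tab$atom)) tab$atom <- "CA"
    frames <- sort(unique(tab$frame))
    resids <- sort(unique(tab$residue))
    nf <- length(frames)
    nr <- length(resids)
    pull <- function(atom) {
      sub <- tab[tab$atom == atom, ]
      if (nrow(sub) == 0L) return(NULL)
      if (nrow(sub) != nf * nr) {
        stop("table is not complete for atom ", atom, call. = FALSE)
      }
      arr <- array(NA_real_, c(nf, nr, 3L))
      fi <- match(sub$frame, frames)
      ri <- match(sub$residue, resids)
      for (k in seq_len(nrow(sub))) {
        arr[fi[k], ri[k], ] <- c(sub$x[k], sub$y[k], sub$z[k])
      }
      arr
    }
    ca <- pull("CA")
    if (is.null(ca)) stop("no CA rows in coordinate table", call. = FALSE)
    traj_ensemble(ca, n_atoms = pull("N"), o_atoms = pull("O"))
  }
}

#' Write a contact map (or any matrix) as CSV
#'
#' @param map A \code{\link{contact_map}} or plain matrix.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_matrix <- function(map, path) {
  m <- if (inherits(map, "contact_map")) map$p else map
  write.csv(as.data.frame(m), path, row.names = !is.null(rownames(m)))
  invisible(path)
}

#' Write an analysis table as CSV / TSV
#'
#' @param tab data.frame.
#' @param path Output path (.tsv writes tab-separated).
#' @return Invisibly, the path.
#' @export
write_table <- function(tab, path) {
  if (grepl("\\.tsv$", path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Resolved run configuration
#'
#' Collects the package defaults with any overrides, plus the package
#' version and seed, for embedding into analysis outputs.
#'
#' @param ... Named overrides.
#' @param seed Integer seed recorded in the manifest.
#' @return Named list.
#' @export
run_config <- function(..., seed = NA_integer_) {
  cfg <- list(window = 3L, cutoff = 0.37, min_blob = 4L,
              blob_contact_cutoff = 0.55, residue_contact_cutoff = 0.8,
              hardcore_a = 0.3, mc_step = 0.5, mc_steps = 5e6,
              sample_every = 100L, min_run = 4L, persistence = 0.06,
              long_range_sep = 20L, z = 3, seed = seed,
              package_version = as.character(utils::packageVersion("idpblob")))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' End-to-end ensemble analysis pipeline
#'
#' Chains the package stages on one sequence + ensemble: blob
#' identification, blob metrics, real-protein contact maps, SAHP
#' parameterization and Monte Carlo run, region segmentation, enrichment,
#' and (when dihedrals are present) the symmetric coupling scan. Outputs
#' are written to a directory with a JSON manifest embedding the resolved
#' configuration.
#'
#' @param seq A \code{sequence_record} (or raw string).
#' @param traj A \code{traj_ensemble}.
#' @param out_dir Output directory (created if missing); NULL skips
#'   writing.
#' @param seed Seed for the SAHP run.
#' @param config Optional \code{\link{run_config}} overrides (list).
#' @return List with \code{partition}, \code{metrics}, \code{rp_map},
#'   \code{sahp_map}, \code{segmentation}, \code{enrichment},
#'   \code{coupling} (or NULL), and \code{config}.
#' @export
analyze_ensemble <- function(seq, traj, out_dir = NULL, seed = 1L,
                             config = list()) {
  cfg <- do.call(run_config, c(config, list(seed = seed)))
  partition <- identify_blobs(seq, cutoff = cfg$cutoff,
                              min_blob = cfg$min_blob, window = cfg$window)
  metrics <- blob_table(partition)
  rp_map <- blob_contact_map(traj, partition,
                             cutoff = cfg$blob_contact_cutoff)
  geom <- blob_geometry(traj, partition)
  model <- sahp_parameterize(geom, classes = partition$blobs$class,
                             a = cfg$hardcore_a, step = cfg$mc_step,
                             cutoff = cfg$blob_contact_cutoff)
  samp <- sahp_run(model, steps = cfg$mc_steps,
                   sample_every = cfg$sample_every, seed = seed,
                   keep_positions = FALSE)
  sahp_map <- sahp_contact_map(samp)
  seg <- segment_regions(sahp_map, model)
  enr <- enrichment(rp_map, sahp_map, regions = seg$regions)
  coup <- NULL
  if (!is.null(traj$phi)) {
    coup <- detect_symmetric_coupling(traj, partition, z = cfg$z,
                                      cutoff = cfg$blob_contact_cutoff,
                                      min_run = cfg$min_run)
  }
  out <- list(partition = partition, metrics = metrics, rp_map = rp_map,
              sahp_map = sahp_map, segmentation = seg, enrichment = enr,
              coupling = coup, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(metrics, file.path(out_dir, "blob_metrics.csv"))
    write_matrix(rp_map, file.path(out_dir, "rp_contact_map.csv"))
    write_matrix(sahp_map, file.path(out_dir, "sahp_contact_map.csv"))
    write_table(enr, file.path(out_dir, "enrichment.csv"))
    if (!is.null(coup)) {
      write_table(coup, file.path(out_dir, "coupling.csv"))
    }
    manifest <- list(config = cfg,
                     blobs = partition$blobs,
                     regions = as.list(seg$regions),
                     n_frames = n_frames(traj))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
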