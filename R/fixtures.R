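# Seeded generators producing every input class the toolkit consumes, with
# known ground truth. One local seeded RNG per generator; callers' RNG state
# is left untouched, and identical (seed, parameters) give identical output.

.NNK_BASES <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                   c("G", "T"))

# draw one stop-free NNK codon
.draw_nnk <- function() {
  repeat {
    cd <- paste0(sample(.NNK_BASES[[1]], 1), sample(.NNK_BASES[[2]], 1),
                 sample(.NNK_BASES[[3]], 1))
    if (cd != "TAG") return(cd)
  }
}

.mutate_bases <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

#' Generate a synthetic 96-colony Sanger run
#'
#' Emulates sequencing of randomly picked colonies from a loop-diversified
#' monobody phagemid library: clones are drawn from `nFamilies` planted
#' families (each with stop-free NNK loops, BC length 5-9 and FG length
#' 7-13), every planted family is represented at least once, a configurable
#' fraction of reads comes off the reverse strand, and per-base substitution
#' errors, 5' truncations and invalid clones (in-loop amber stops, destroyed
#' NotI sites) are injected at the stated rates.
#'
#' @param nReads number of colony reads (default 96).
#' @param nFamilies number of planted clone families (default 11).
#' @param seed RNG seed; identical seed and parameters give identical
#'   output.
#' @param errorRate per-base substitution rate (default 0.002,
#'   Sanger-like).
#' @param reverseFraction fraction of reads reported on the reverse strand.
#' @param stopRate fraction of reads given an in-loop amber stop.
#' @param siteLossRate fraction of reads with a destroyed NotI site.
#' @param truncationRate fraction of reads truncated at the 5' end.
#' @param scaffold a [ScaffoldTemplate-class].
#' @param design a [LibraryDesign-class] giving loop length ranges.
#' @param fasta optional path; when given the reads are also written as
#'   multi-FASTA.
#' @return list with `reads` (named character), `truth` (planted families,
#'   per-read family assignment and per-read corruption flags).
#' @export
genLibraryReads <- function(nReads = 96L, nFamilies = 11L, seed = 1L,
                            errorRate = 0.002, reverseFraction = 0.5,
                            stopRate = 0, siteLossRate = 0,
                            truncationRate = 0,
                            scaffold = fn3Scaffold(),
                            design = fn3LibraryDesign(scaffold),
                            fasta = NULL) {
  stopifnot(nFamilies >= 1, nReads >= nFamilies)
  ranges <- lapply(design@loops, function(lp) lp@lengthRange)
  names(ranges) <- vapply(design@loops, function(lp) lp@loopId, character(1))
  out <- with_seed(seed, {
    families <- lapply(seq_len(nFamilies), function(k) {
      loops <- lapply(ranges, function(r) {
        L <- sample(r[1]:r[2], 1)
        dna <- paste(vapply(seq_len(L), function(i) .draw_nnk(),
                            character(1)), collapse = "")
        list(dna = dna, peptide = .translate_from(dna, 0L))
      })
      loops
    })
    assignment <- c(seq_len(nFamilies),
                    sample.int(nFamilies, nReads - nFamilies,
                               replace = TRUE))
    assignment <- sample(assignment)  # shuffle read order
    flags <- data.frame(reverse = runif(nReads) < reverseFraction,
                        stopped = runif(nReads) < stopRate,
                        siteLost = runif(nReads) < siteLossRate,
                        truncated = runif(nReads) < truncationRate)
    reads <- character(nReads)
    for (i in seq_len(nReads)) {
      fam <- families[[assignment[i]]]
      dna <- scaffold@dna
      for (id in names(ranges)) {
        lp <- scaffold@loops[[id]]
        loop_dna <- fam[[id]]$dna
        if (flags$stopped[i] && id == names(ranges)[1]) {
          # plant an amber stop in the first variable codon
          loop_dna <- paste0("TAG", substr(loop_dna, 4, nchar(loop_dna)))
        }
        dna <- sub(paste0(lp$anchor5, ".*?", lp$anchor3),
                   paste0(lp$anchor5, loop_dna, lp$anchor3), dna,
                   perl = TRUE)
      }
      if (flags$siteLost[i])
        dna <- sub(scaffold@requiredSites[["NotI"]], "ACGGCCGC", dna,
                   fixed = TRUE)
      if (flags$truncated[i])
        dna <- substr(dna, sample(2:30, 1), nchar(dna))
      dna <- .mutate_bases(dna, errorRate)
      if (flags$reverse[i]) dna <- .revcomp(dna)
      reads[i] <- dna
    }
    names(reads) <- sprintf("colony_%03d", seq_len(nReads))
    list(reads = reads,
         truth = list(families = families, assignment = assignment,
                      flags = flags))
  })
  if (!is.null(fasta)) {
    set <- Biostrings::DNAStringSet(out$reads)
    Biostrings::writeXStringSet(set, fasta)
  }
  out
}

#' Generate synthetic titration bundles
#'
#' Produces one noisy dataset per binding-assay class -- single-cycle SPR
#' sensorgram, ITC isotherm (0.5 uL pre-injection + 29 x 1 uL), direct FP
#' titration (50 nM tracer), competitive FP curve and competitive pull-down
#' densitometry (duplicate lanes) -- from planted parameters, plus the truth
#' record. Signals are model-generated with additive Gaussian noise at the
#' stated levels; geometries follow the standard instrument protocols.
#'
#' @param seed RNG seed.
#' @param kon,koff,Rmax planted SPR parameters (1/(M s), 1/s, RU).
#' @param topConc top SPR analyte concentration (M).
#' @param sckNoise sensorgram noise s.d. (RU).
#' @param itcKd,itcDh,itcN planted ITC parameters (M, kcal/mol, sites).
#' @param cellConc,syringeConc ITC cell and syringe concentrations (M).
#' @param itcNoiseFrac ITC heat noise as a fraction of the largest heat.
#' @param fpKd planted direct-FP dissociation constant (M).
#' @param fpKi planted competitive-FP inhibition constant (M).
#' @param pdKi planted pull-down inhibition constant (M).
#' @param tracerConc tracer concentration (M).
#' @param fpNoise FP noise s.d. (mP).
#' @param pdNoiseFrac pull-down intensity noise fraction.
#' @param biphasic add a second kinetic component to the sensorgram (a
#'   constructed violation of the 1:1 model).
#' @param dir optional directory: CSV files and a truth JSON are written.
#' @return list with `sensorgram` ([Sensorgram-class]), `itc`
#'   ([ItcExperiment-class]), `fpDirect` ([FpTitration-class]),
#'   `fpCompetition`, `pulldown` ([CompetitionCurve-class]) and `truth`.
#' @export
genTitrations <- function(seed = 1L, kon = 9.5e4, koff = 0.4, Rmax = 20,
                          topConc = 8e-6, sckNoise = 0.5,
                          itcKd = 67e-9, itcDh = -10, itcN = 1,
                          cellConc = 28e-6, syringeConc = 0.30e-3,
                          itcNoiseFrac = 0.02,
                          fpKd = 330e-9, fpKi = 1e-6, pdKi = 50e-9,
                          tracerConc = 50e-9, fpNoise = 1,
                          pdNoiseFrac = 0.05, biphasic = FALSE,
                          dir = NULL) {
  with_seed(seed, {
    # --- SPR ---
    sg <- simulateSck(kon, koff, Rmax, topConc = topConc)
    d <- sg@data
    if (biphasic) {
      sg2 <- simulateSck(kon / 30, koff / 50, Rmax, topConc = topConc)
      d$response <- 0.6 * d$response + 0.4 * sg2@data$response
    }
    d$response <- d$response + rnorm(nrow(d), 0, sckNoise)
    sensor <- sensorgram(d)
    # --- ITC ---
    geom <- itcExperiment(cellConc, syringeConc)
    heats <- itcIsotherm(itcN, itcKd, itcDh, geom)
    heats <- heats + rnorm(length(heats), 0, itcNoiseFrac * max(abs(heats)))
    itc <- itcExperiment(cellConc, syringeConc, heats = heats)
    # --- FP direct ---
    rt <- 10^seq(-8.5, -4, length.out = 12)
    fb <- fpBoundFraction(fpKd, rt, tracerConc)
    mp <- 60 + (240 - 60) * fb + rnorm(length(rt), 0, fpNoise)
    fpd <- fpTitration(rt, mp, tracerConc)
    # --- FP competition (receptor set near 75% bound tracer) ---
    rt75 <- 10^uniroot(function(lR)
      fpBoundFraction(fpKd, 10^lR, tracerConc) - 0.75,
      c(-12, -2), tol = 1e-10)$root
    it <- c(0, 10^seq(-9, -3.5, length.out = 11))
    fbi <- competitionEquilibrium(rt75, tracerConc, it, fpKd,
                                  fpKi)$tracerBoundFraction
    mpc <- 60 + (240 - 60) * fbi + rnorm(length(it), 0, fpNoise)
    fpc <- competitionCurve(it, mpc, rt75, tracerConc, fpKd)
    # --- pull-down (duplicate lanes, percent of the 0-competitor lane) ---
    pdTracer <- 120e-9   # immobilized divalent ligand in the bead assay
    pdTracerKd <- 10 * pdKi
    shift <- 1 + pdTracer / pdTracerKd
    ic50 <- pdKi * shift
    conc <- c(0, 10^seq(-9, -5, length.out = 9))
    lanes <- rep(conc, each = 2)
    frac <- ifelse(lanes == 0, 1,
                   1 / (1 + lanes / ic50))
    inten <- 100 * frac * (1 + rnorm(length(lanes), 0, pdNoiseFrac))
    pd <- competitionCurve(lanes, inten, 180e-9, pdTracer, pdTracerKd)
    truth <- list(kon = kon, koff = koff, Rmax = Rmax, itcKd = itcKd,
                  itcDh = itcDh, itcN = itcN, fpKd = fpKd, fpKi = fpKi,
                  pdKi = pdKi, tracerConc = tracerConc,
                  biphasic = biphasic, seed = seed)
    out <- list(sensorgram = sensor, itc = itc, fpDirect = fpd,
                fpCompetition = fpc, pulldown = pd, truth = truth)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write.csv(sensor@data, file.path(dir, "sensorgram.csv"),
                row.names = FALSE)
      write.csv(data.frame(injection = seq_along(itc@heats),
                           volume_uL = itc@injectionVolumes * 1e6,
                           heat_ucal = itc@heats),
                file.path(dir, "itc.csv"), row.names = FALSE)
      write.csv(data.frame(receptor_M = rt, mP = mp),
                file.path(dir, "fp_direct.csv"), row.names = FALSE)
      write.csv(data.frame(competitor_M = it, mP = mpc),
                file.path(dir, "fp_competition.csv"), row.names = FALSE)
      write.csv(data.frame(competitor_M = lanes,
                           lane = seq_along(lanes), intensity = inten),
                file.path(dir, "pulldown.csv"), row.names = FALSE)
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  })
}

#' Generate synthetic free/bound chemical-shift tables
#'
#' Baseline amide shifts for `nResidues` residues, with a contiguous
#' planted epitope patch perturbed in both dimensions and an optional
#' broadened subset flagged in the bound state.
#'
#' @param nResidues residue count (>= 10).
#' @param patchStart,patchLength planted contiguous epitope patch.
#' @param amplitude15N,amplitude1HN patch perturbations (ppm).
#' @param broadened residue numbers flagged broadened in the bound state.
#' @param noise s.d. of incidental shift differences (ppm).
#' @param seed RNG seed.
#' @param dir optional directory for `shifts_free.csv` / `shifts_bound.csv`.
#' @return list with `free`, `bound` (shift tables) and `truth` (planted
#'   patch and broadened residues).
#' @export
genShiftTables <- function(nResidues = 90L, patchStart = 30L,
                           patchLength = 12L, amplitude15N = 1.0,
                           amplitude1HN = 0.2, broadened = integer(0),
                           noise = 0.005, seed = 2L, dir = NULL) {
  stopifnot(nResidues >= 10,
            patchStart + patchLength - 1 <= nResidues)
  with_seed(seed, {
    res <- seq_len(nResidues)
    aa3 <- c("ALA", "GLY", "LEU", "SER", "THR", "VAL", "ASP", "GLU", "LYS",
             "ARG")
    free <- data.frame(residue = res,
                       resname = sample(aa3, nResidues, replace = TRUE),
                       d1HN = runif(nResidues, 7.5, 9.5),
                       d15N = runif(nResidues, 105, 130),
                       broadened = FALSE, missing = FALSE,
                       ambiguous = FALSE, stringsAsFactors = FALSE)
    patch <- seq(patchStart, patchStart + patchLength - 1L)
    bound <- free
    bound$d1HN <- bound$d1HN + rnorm(nResidues, 0, noise)
    bound$d15N <- bound$d15N + rnorm(nResidues, 0, noise)
    sgn <- sample(c(-1, 1), patchLength, replace = TRUE)
    bound$d1HN[patch] <- bound$d1HN[patch] + sgn * amplitude1HN
    bound$d15N[patch] <- bound$d15N[patch] + sgn * amplitude15N
    bound$broadened[bound$residue %in% broadened] <- TRUE
    truth <- list(patch = patch, broadened = broadened, seed = seed)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write.csv(free, file.path(dir, "shifts_free.csv"), row.names = FALSE)
      write.csv(bound, file.path(dir, "shifts_bound.csv"),
                row.names = FALSE)
    }
    list(free = free, bound = bound, truth = truth)
  })
}

#' Simulate serial-dilution plating of a known titer
#'
#' Poisson colony counts for a dilution series of a phage stock, for
#' exercising the titer estimators against a planted truth.
#'
#' @param titer true titer (cfu/mL).
#' @param dilutions dilution factors.
#' @param platedVolume plated volume per plate (mL).
#' @param seed RNG seed.
#' @return data.frame with `dilution`, `colonies`, plus attribute `truth`.
#' @export
genDilutionSeries <- function(titer = 1e8,
                              dilutions = 10^(3:7), platedVolume = 0.01,
                              seed = 3L) {
  with_seed(seed, {
    lam <- titer * platedVolume / dilutions
    out <- data.frame(dilution = dilutions, colonies = rpois(length(lam),
                                                             lam))
    attr(out, "truth") <- titer
    out
  })
}
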