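# Small in-code fixtures shared across test files.

# minimal two-drug registry for hand-built plates
tiny_registry <- function() {
  drug_registry(c("Cisplatin", "Paclitaxel"),
                cmax_uM = c(13.67, 5.10),
                secondary_start_uM = c(50, 50))
}

# preliminary plate in long format: one organoid, chosen viabilities, NC = 1000
prelim_wells <- function(viabilities, organoid = "ORG1", nc_signal = 1000,
                         registry = load_registry("table2"), reps = 3L) {
  drugs <- names(viabilities)
  rows <- lapply(drugs, function(d) {
    data.frame(organoid_id = organoid, drug = d,
               concentration_uM = registry_drug(registry, d)$cmax_uM,
               timepoint = "TEND", replicate = seq_len(reps),
               signal = nc_signal * viabilities[[d]])
  })
  nc <- data.frame(organoid_id = organoid, drug = "NC", concentration_uM = 0,
                   timepoint = "TEND", replicate = seq_len(reps),
                   signal = nc_signal)
  screen_dataset(rbind(do.call(rbind, rows), nc), "PRELIMINARY", registry)
}

# noiseless gr_profile built directly from a truth sigmoid on a titration
truth_profile <- function(gr_inf, gec50, hill, start = 50, n = 6,
                          organoid = "ORG1", drug = "Cisplatin") {
  conc <- start / 4^(seq_len(n) - 1)
  structure(list(
    organoid_id = organoid, drug = drug,
    points = data.frame(concentration_uM = conc,
                        gr = gr_curve(conc, gr_inf, gec50, hill),
                        gr_sd = NA_real_,
                        viability = NA_real_,
                        n_replicates = 1L),
    replicate_gr = NULL, x0 = NA_real_, x_ctrl = NA_real_
  ), class = "gr_profile")
}

# independent brute-force trapezoid over log10 concentration (loop form)
oracle_norm_auc <- function(conc, viability) {
  ord <- order(conc)
  x <- log10(conc[ord])
  v <- pmin(pmax(viability[ord], 0), 1)
  area <- 0
  for (i in seq_len(length(x) - 1)) {
    area <- area + (x[i + 1] - x[i]) * (v[i] + v[i + 1]) / 2
  }
  area / (x[length(x)] - x[1])
}

# independent all-pairs ROC AUC (positive class = is_pos, higher score wins)
oracle_pairs_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
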