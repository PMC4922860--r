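#!/usr/bin/env Rscript
# Whole-cell Ca2+ accumulation under repetitive 0.5 Hz ramps: the coupled
# model links Ca2+ entry through the channel, chelator buffering, E_Ca and
# the potentiation/inactivation fate of the current — contrasting 5 mM BAPTA
# with the 15 mM BAPTA + 5 mM EGTA high-buffer condition.

suppressPackageStartupMessages(library(pkdclamp))
dir.create("results", showWarnings = FALSE)

pot <- list(g_max = 3, K_pot_nM = 300, hill = 2)
wt <- gating_preset("wt", n_channels = 2000, potentiation = pot)

run <- function(minutes, buffers, initial_free_nM, label) {
  prot <- make_protocol("ramp-0.5hz", n_sweeps = minutes * 30,
                        sample_interval = 1e-3)
  cw <- coupled_whole_cell(prot, wt, buffers = buffers,
                           initial_free_nM = initial_free_nM)
  s <- cw$summary
  s$condition <- label
  s
}

s5 <- run(8, list(buffer_spec("BAPTA", 5, 0.22)), 100, "BAPTA-5mM")
s20 <- run(10, list(buffer_spec("BAPTA", 15, 0.22),
                    buffer_spec("EGTA", 5, 0.15)), 15, "BAPTA15-EGTA5")
both <- rbind(s5, s20)
write.csv(both, "results/accumulation.csv", row.names = FALSE)

report <- function(s, label) {
  peak_sweep <- which.max(s$peak_out_pA)
  cat(sprintf("%s: peak current %.2f nA at %.1f min (%.1fx potentiation);\n",
              label, s$peak_out_pA[peak_sweep] / 1000,
              s$time[peak_sweep] / 60,
              s$peak_out_pA[peak_sweep] / s$peak_out_pA[1]))
  cat(sprintf("  end of run: free Ca2+ %.3g uM, E_Ca %.1f mV, fraction inactivated %.3f\n",
              s$free_ca_uM[nrow(s)], s$e_ca_mV[nrow(s)], s$p_I[nrow(s)]))
}
report(s5, "5 mM BAPTA (8 min)")
report(s20, "15 mM BAPTA + 5 mM EGTA (10 min)")

over10 <- which(s5$free_ca_uM > 10)[1]
cat(sprintf("\n5 mM BAPTA saturates: free Ca2+ exceeds 10 uM at %.1f min;\n",
            s5$time[over10] / 60))
cat("once the ramp peak is positive to E_Ca, outward block and k2 = 1/2.1 /s\n")
cat("inactivation remove the current irreversibly. The high-buffer condition\n")
cat("keeps free Ca2+ sub-micromolar, E_Ca above the ramp, and the current\n")
cat("potentiated but intact over the full 10 min.\n")
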