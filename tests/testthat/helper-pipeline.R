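# One small synthetic screen written to disk in the external file formats,
# shared by the pipeline and reproduction-pathway tests.
write_pipeline_inputs <- function(dir, seed = 902, n_screen_drugs = 16,
                                  n_panel_drugs = 12, n_kinases = 10,
                                  n_cytokines = 3, k_planted = 2,
                                  noise_sd = 0.01) {
  cfg <- sim_config(n_screen_drugs = n_screen_drugs,
                    n_panel_drugs = n_panel_drugs, n_kinases = n_kinases,
                    n_cytokines = n_cytokines, k_planted = k_planted,
                    noise_sd = noise_sd, seed = seed)
  sim <- simulate_screen(cfg)
  paths <- list(x = file.path(dir, "x_screen.tsv"),
                y = file.path(dir, "y_screen.tsv"),
                panel = file.path(dir, "x_panel.tsv"),
                ann = file.path(dir, "annotations.tsv"),
                net = file.path(dir, "network.tsv"),
                secr = file.path(dir, "secretome.tsv"))
  write_matrix(sim$x_screen, paths$x, id_name = "drug")
  write_matrix(sim$y_screen, paths$y, id_name = "drug")
  write_matrix(sim$x_panel, paths$panel, id_name = "drug")
  write.table(data.frame(drug_id = rownames(sim$x_panel),
                         fda_approved = rep_len(c(TRUE, FALSE),
                                                nrow(sim$x_panel))),
              paths$ann, sep = "\t", quote = FALSE, row.names = FALSE)
  # reference graph: each cytokine anchored to its planted kinases plus a
  # connector edge
  set.seed(seed)
  edges <- do.call(rbind, lapply(names(sim$ground_truth$support), function(cy) {
    sup <- sim$ground_truth$support[[cy]]
    if (!length(sup)) return(NULL)
    data.frame(from = cy, to = sup,
               weight = round(runif(length(sup), 0.1, 1), 3))
  }))
  edges <- rbind(edges, data.frame(from = "K001", to = "K002", weight = 0.5))
  write.table(edges, paths$net, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tab <- simulate_secretome(n_factors = 30, n_changed = 5, n_replicates = 3,
                            seed = seed)
  write.table(tab, paths$secr, sep = "\t", quote = FALSE, row.names = FALSE)
  list(paths = paths, sim = sim, config = cfg)
}
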