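# Build a complete on-disk synthetic experiment: one point-geometry
# condition, one planar (membrane) condition, a Zn-style control and a
# set of metal-free mocks, all at pH 8, plus config YAML.
make_pipeline_fixture <- function(root, n_cells = 10, seed = 123,
                                  q_point = 0.2, d_planar = 10,
                                  R0_point = 17.6, R0_planar = 12.4,
                                  sigma = 0.002, bleach = 0.9,
                                  signal = 1e4) {
  img_dir <- file.path(root, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  q_planar <- planar_efficiency(d_planar, R0_planar, sigma)
  specs <- list(
    point = list(q = q_point, donor = "E8", acceptor = "C469",
                 control = 0, mock = 0),
    planar = list(q = q_planar, donor = "E8", acceptor = "membrane",
                  control = 0, mock = 0),
    control = list(q = 0, donor = "E8", acceptor = "C469zn",
                   control = 1, mock = 0),
    mock = list(q = 0, donor = "E8", acceptor = "none",
                control = 0, mock = 1))
  rois <- list(); meta <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    bun <- gen_imaging_bundle(n_cells, quench = sp$q, bleach = bleach,
                              signal = signal, seed = seed + k)
    ids <- paste0(names(specs)[k], "_", bun$rois$cell_id)
    names(bun$stacks) <- ids
    bun$rois$cell_id <- ids
    for (id in ids)
      write_image_stack(bun$stacks[[id]], file.path(img_dir,
                                                    paste0(id, ".txt")))
    rois[[k]] <- bun$rois
    meta[[k]] <- data.frame(cell_id = ids, donor_site = sp$donor,
                            acceptor = sp$acceptor, pH = 8,
                            is_control = sp$control, is_mock = sp$mock)
  }
  roi_csv <- file.path(root, "rois.csv")
  meta_csv <- file.path(root, "metadata.csv")
  utils::write.csv(do.call(rbind, rois), roi_csv, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(do.call(rbind, meta), meta_csv, row.names = FALSE,
                   quote = FALSE)
  config <- list(
    input = list(image_dir = img_dir, roi_csv = roi_csv,
                 metadata_csv = meta_csv),
    constants = list(r0 = list(pH8 = R0_point),
                     r0_planar = list(pH8 = R0_planar),
                     sigma = sigma, d_floor = 5, model = "average"),
    out_dir = file.path(root, "out"),
    seed = seed)
  cfg_path <- file.path(root, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  list(config = cfg_path, config_list = config,
       truth = list(q_point = q_point, q_planar = q_planar,
                    d_planar = d_planar,
                    r_point = R0_point * (1 / q_point - 1)^(1 / 6)))
}
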