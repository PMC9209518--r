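# Named presets encoding the experimental conditions emulated by the synthetic
# generators. Numbers not printed in the source experiments (intensity scales,
# noise levels, calibrated event rates) live here, never hard-coded in code.
frap:
  # TALE-MSR reporter: 1 frame/s for 310 s, 10 pre-bleach frames.
  # Control recovery reaches 50% of pre-bleach within ~30 s (K = ln2/30) and
  # leaves ~25% immobile.
  tale_ctrl:
    pre_bleach_frames: 10
    frame_interval_s: 1.0
    post_interval_s: 1.0
    n_frames: 310
    bleach_depth: 0.30
    mobile_fraction: 0.75
    k_per_s: 0.0231049
    acq_bleach_per_s: 0.0005
    noise_sd: 0.02
  # MSR-depleted: recovery time doubles, mobile fraction slightly lower.
  tale_msr:
    pre_bleach_frames: 10
    frame_interval_s: 1.0
    post_interval_s: 1.0
    n_frames: 310
    bleach_depth: 0.30
    mobile_fraction: 0.70
    k_per_s: 0.0115525
    acq_bleach_per_s: 0.0005
    noise_sd: 0.02
  # HP1a-Eos reporter: 2 pre-bleach frames at 1 s, then one frame every 5 s
  # for 61 s. Control: t_half = 8 s, immobile 15%; MSR-depleted: t_half = 13 s,
  # immobile 26%.
  hp1a_ctrl:
    pre_bleach_frames: 2
    frame_interval_s: 1.0
    post_interval_s: 5.0
    n_frames: 15
    bleach_depth: 0.35
    mobile_fraction: 0.85
    k_per_s: 0.0866434
    acq_bleach_per_s: 0.002
    noise_sd: 0.02
  hp1a_msr:
    pre_bleach_frames: 2
    frame_interval_s: 1.0
    post_interval_s: 5.0
    n_frames: 15
    bleach_depth: 0.35
    mobile_fraction: 0.74
    k_per_s: 0.0533188
    acq_bleach_per_s: 0.002
    noise_sd: 0.02

dynamics:
  # Time-lapse condition: one frame every 30 s for 20 min. Fusion/fission
  # rates (events per focus per minute) were calibrated once by simulation so
  # that the measured per-cell engagement of >=10-min tracks matches the
  # target fraction, then frozen.
  ctrl_dynamics:
    n_foci: 11
    d_app: 5.0e-4
    alpha: 0.7
    velocity: 0.0
    fusion_rate: 0.0100
    fission_rate: 0.0100
    frame_interval_s: 30.0
    duration_s: 1200.0
    event_engagement_target: 0.45
  # MSR-depleted nuclei contain more, smaller chromocenters (fragmentation),
  # hence the larger focus count.
  msr_dynamics:
    n_foci: 14
    d_app: 2.0e-4
    alpha: 0.6
    velocity: 0.0
    fusion_rate: 0.0048
    fission_rate: 0.0048
    frame_interval_s: 30.0
    duration_s: 1200.0
    event_engagement_target: 0.25
  # Displacement condition: one frame per second for 310 frames, no events.
  ctrl_displacement:
    n_foci: 8
    d_app: 5.0e-4
    alpha: 0.7
    velocity: 0.0
    fusion_rate: 0.0
    fission_rate: 0.0
    frame_interval_s: 1.0
    duration_s: 309.0
    event_engagement_target: 0.0
  msr_displacement:
    n_foci: 8
    d_app: 2.0e-4
    alpha: 0.6
    velocity: 0.0
    fusion_rate: 0.0
    fission_rate: 0.0
    frame_interval_s: 1.0
    duration_s: 309.0
    event_engagement_target: 0.0

nucleus:
  # Interphase ESC nucleus, mid-section view, 0.1 um pixels. RNA focus
  # localization probabilities (within, periphery, between) for the control
  # gapmer condition: (0.17, 0.64, 0.19).
  gfp_gapmer:
    image_shape: [160, 160]
    voxel_size_um: 0.1
    n_chromocenters: {mean: 8, sd: 1.5, min: 5}
    cc_radius_um: {mean: 1.0, sd: 0.12, min: 0.6}
    cc_intensity: 180.0
    eu_intensity: 60.0
    background: 10.0
    h3k9me3_scale: 1.0
    hp1a_scale: 1.0
    rna_foci_count: {mean: 5, sd: 1.0, min: 2}
    rna_radius_um: 0.35
    rna_intensity: 150.0
    rna_class_probs: [0.17, 0.64, 0.19]
    psf_sigma_um: 0.15
    noise_sd: 4.0
  # MSR-depleted nuclei: more numerous, smaller chromocenters; MSR RNA foci
  # largely absent.
  msr_gapmer:
    image_shape: [160, 160]
    voxel_size_um: 0.1
    n_chromocenters: {mean: 14, sd: 2.0, min: 8}
    cc_radius_um: {mean: 0.75, sd: 0.10, min: 0.5}
    cc_intensity: 180.0
    eu_intensity: 60.0
    background: 10.0
    h3k9me3_scale: 1.5
    hp1a_scale: 1.2
    rna_foci_count: {mean: 0.3, sd: 0.5, min: 0}
    rna_radius_um: 0.35
    rna_intensity: 150.0
    rna_class_probs: [0.17, 0.64, 0.19]
    psf_sigma_um: 0.15
    noise_sd: 4.0
  # Projected live-cell field used by the time-lapse generator (0.25 um px).
  timelapse_nucleus:
    image_shape: [80, 80]
    voxel_size_um: 0.25
    nucleus_radius_um: 7.0
    cc_radius_um: {mean: 0.6, sd: 0.0, min: 0.6}
    cc_intensity: 600.0
    eu_intensity: 40.0
    background: 10.0
    psf_sigma_um: 0.12
    noise_sd: 3.0

droplets:
  # In vitro HP1a droplet plate. Concentrations on the 2x-label scale of the
  # dilution series (200 uM two-fold down to 1.6 uM, plus 0); final 1x
  # concentrations after equal-volume mixing are half these labels.
  # Forward-strand transcripts yield larger droplets than reverse-strand at
  # matched repeat number; longer repeats lower the critical concentration;
  # HP1a alone (no RNA) never forms droplets.
  msr_plate:
    protein_concs_uM: [200, 100, 50, 25, 12.5, 6.2, 3.1, 1.6, 0]
    rna_species:
      - {name: msr_1f, critical_conc_uM: 50.0,  droplet_size_scale_um: 4.5}
      - {name: msr_1r, critical_conc_uM: 50.0,  droplet_size_scale_um: 3.0}
      - {name: msr_4f, critical_conc_uM: 12.5,  droplet_size_scale_um: 6.0}
      - {name: msr_4r, critical_conc_uM: 12.5,  droplet_size_scale_um: 4.0}
      - {name: msr_8f, critical_conc_uM: 6.2,   droplet_size_scale_um: 7.0}
      - {name: msr_8r, critical_conc_uM: 6.2,   droplet_size_scale_um: 4.7}
      - {name: polyU,  critical_conc_uM: 12.5,  droplet_size_scale_um: 5.0}
      - {name: no_rna, critical_conc_uM: .inf,  droplet_size_scale_um: 4.5}
    field_shape_px: [256, 256]
    pixel_size_um: 0.5
    droplet_count_mean: 25
    droplet_count_min: 5
    background: 8.0
    droplet_intensity: 120.0
    noise_sd: 3.0

flim:
  # SiR-DNA lifetimes (ns). Shorter lifetime = more compact chromatin;
  # heterochromatin is more compact than euchromatin, and MSR depletion
  # compacts chromatin further (larger drop in heterochromatin).
  sirdna:
    rep_period_ns: 25.0
    n_bins: 256
    tau_eu_ns:
      gfp_gapmer: 2.40
      msr_gapmer: 2.35
    tau_het_ns:
      gfp_gapmer: 2.00
      msr_gapmer: 1.90
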