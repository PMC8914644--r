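# Coral mini Dev board with Edge TPU acceleration.
device: Coral mini Dev (TPU)
sleep_current_mA: 240
phases:
  - name: capture_with_flash
    current_mA: 400
    duration_s: 0.062
  - name: inference
    current_mA: 460
    duration_s: 0.036
  - name: store_sd_wifi_upload
    current_mA: 450
    duration_s: 0.076
  - name: other_functions
    current_mA: 240
    duration_s: 62.826
battery_capacity_mAh: 6700
cycles_per_day: 1
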