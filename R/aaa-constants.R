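# Column dialect shared by the generator, the readers/writers and the
# windowing pipeline. Defined first in collation order.
STREAM_COLUMNS <- c("timestamp", "acc_x", "acc_y", "acc_z",
                    "gyr_x", "gyr_y", "gyr_z",
                    "mag_x", "mag_y", "mag_z",
                    "light", "tod", "missing")

CHANNEL_COLUMNS <- setdiff(STREAM_COLUMNS, c("timestamp", "missing"))

EVENT_KINDS <- c("smoke", "lapse", "craving")

TIME_FORMAT <- "%Y-%m-%dT%H:%M:%S"
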