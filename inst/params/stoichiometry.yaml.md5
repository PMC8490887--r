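49090c7af0f4c4ca99918de8467eed89
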