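bad
sad
angry
upset
worried
anxious
afraid
scared
fear
nervous
tired
terrible
awful
horrible
worse
worst
hate
annoyed
frustrated
lonely
depressed
hopeless
pain
hurt
sick
stress
stressed
difficult
hard
problem
problems
trouble
troubled
cry
crying
miserable
unhappy
empty
numb
paranoid
confused
restless
irritable
guilty
ashamed
worthless
dark
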