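good
great
happy
glad
fine
better
best
love
enjoy
hope
hopeful
calm
relaxed
peaceful
nice
wonderful
pleasant
cheerful
excited
proud
grateful
thankful
comfortable
friendly
kind
helpful
improved
improving
easy
fun
laugh
laughed
smile
smiled
satisfied
content
strong
stronger
clear
clearer
rested
cheerful
bright
steady
settled
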